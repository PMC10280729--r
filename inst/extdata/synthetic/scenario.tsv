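key	value
horizon	15
description	synthetic 18-metabolite network, fully labeled source
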