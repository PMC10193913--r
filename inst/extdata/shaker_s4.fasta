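>Shaker S4 voltage-sensor motif, charge-anchored numbering offset=361
RVIRLVRVFRIFKLSRHSKG
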