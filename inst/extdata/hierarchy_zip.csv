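13185;131**;*
13186;131**;*
13187;131**;*
13188;131**;*
13189;131**;*
13190;131**;*
13191;131**;*
13192;131**;*
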