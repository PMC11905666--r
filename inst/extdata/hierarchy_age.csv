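30;30-34;30-39;*
31;30-34;30-39;*
32;30-34;30-39;*
33;30-34;30-39;*
34;30-34;30-39;*
35;35-39;30-39;*
36;35-39;30-39;*
37;35-39;30-39;*
38;35-39;30-39;*
39;35-39;30-39;*
40;40-44;40-49;*
41;40-44;40-49;*
42;40-44;40-49;*
43;40-44;40-49;*
44;40-44;40-49;*
45;45-49;40-49;*
46;45-49;40-49;*
47;45-49;40-49;*
48;45-49;40-49;*
49;45-49;40-49;*
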