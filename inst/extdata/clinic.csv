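age,sex,zip,diagnosis
37,male,13186,asthma
39,female,13186,diabetes
32,female,13185,asthma
33,female,13186,asthma
39,male,13187,diabetes
31,female,13186,diabetes
36,male,13189,asthma
49,male,13186,hypertension
34,male,13189,hypertension
39,female,13187,hypertension
31,male,13192,diabetes
37,female,13190,hypertension
34,female,13190,hypertension
40,male,13189,asthma
32,female,13186,diabetes
30,male,13190,hypertension
39,male,13187,asthma
31,male,13188,asthma
33,male,13188,asthma
31,female,13192,diabetes
33,male,13188,diabetes
30,female,13189,diabetes
34,female,13186,asthma
31,female,13189,hypertension
30,female,13188,asthma
34,male,13191,hypertension
30,male,13189,diabetes
32,female,13186,diabetes
31,female,13192,diabetes
38,female,13190,asthma
48,male,13191,diabetes
34,female,13191,diabetes
43,female,13192,hypertension
31,male,13185,hypertension
39,female,13189,diabetes
30,female,13188,diabetes
34,male,13188,asthma
36,female,13192,asthma
42,female,13188,diabetes
36,female,13192,hypertension
30,male,13192,diabetes
49,male,13187,asthma
36,female,13187,diabetes
36,male,13190,diabetes
31,female,13192,asthma
31,female,13190,diabetes
47,female,13190,hypertension
33,female,13190,hypertension
35,female,13185,asthma
34,male,13189,asthma
45,female,13192,hypertension
38,male,13188,asthma
46,male,13187,diabetes
48,male,13189,asthma
35,female,13187,asthma
43,male,13191,diabetes
43,male,13189,diabetes
31,male,13190,diabetes
46,female,13187,hypertension
34,male,13187,diabetes
33,male,13191,diabetes
48,female,13189,diabetes
39,female,13186,diabetes
36,female,13190,hypertension
30,female,13187,asthma
31,female,13191,hypertension
38,female,13187,diabetes
36,female,13188,hypertension
39,male,13186,asthma
37,female,13192,asthma
49,female,13192,asthma
30,male,13186,asthma
43,female,13188,hypertension
49,female,13190,asthma
34,male,13187,hypertension
38,male,13190,asthma
43,male,13188,diabetes
35,male,13189,diabetes
34,female,13192,diabetes
48,female,13190,diabetes
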