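interval,count_early,count_late
0-5%,100,251
5-10%,169,392
10-15%,176,302
15-20%,157,384
20-25%,115,302
25-30%,167,328
30-35%,185,390
35-40%,199,451
40-45%,221,384
45-50%,247,333
50-55%,240,301
55-60%,193,315
60-65%,303,311
65-70%,285,549
70-75%,261,463
75-80%,344,691
80-85%,797,794
85-90%,777,774
90-95%,1039,894
95-100%,4513,1805
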