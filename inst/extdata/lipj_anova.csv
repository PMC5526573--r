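term,ss,df,ms,f,p
pH (L),0.01655,1,0.01655,0.01931,0.902203
pH (Q),49.47081,1,49.47081,57.74358,0.016881
Temp (L),2.03925,1,2.03925,2.38026,0.262839
Temp (Q),29.32510,1,29.32510,34.22900,0.027994
1L by 2L,0.03454,1,0.03454,0.04031,0.859435
Lack of Fit,1.96037,3,0.65346,0.76273,0.610212
Pure Error,1.71347,2,0.85673,,
Total SS,67.49368,10,,,
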