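gene_id,t0,t5,t10,t15,t20,t30,t40,t50,t60
YEX001,1,0.86070797642505781,0.74081822068171788,0.63762815162177333,0.54881163609402639,0.40656965974059917,0.30119421191220214,0.22313016014842982,0.16529888822158656
YFS002,1,0.47044653949666976,0.34287411146647401,0.30338258342698632,0.28363134798427803,0.25537984722431278,0.23101754994929058,0.20903049648564281,0.18913848085041018
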