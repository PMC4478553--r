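sample_id,breed_type,sex,cnv_count,total_length_mb
A1,Asian wild boar,F,180,13.52
DN1,Diannan small-ear,M,144,11.90
DN5,Diannan small-ear,F,229,12.64
M2,Min,F,153,12.14
MS7,Meishan,F,211,9.92
MS8,Meishan,F,224,9.98
R2,Rongchang,M,262,10.78
W1,Daweizi,F,118,8.30
Z2,Tibetan,F,291,14.26
Z5,Tibetan,F,260,12.05
C3,Landrace,F,139,9.78
Y2,Yorkshire,F,65,10.23
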