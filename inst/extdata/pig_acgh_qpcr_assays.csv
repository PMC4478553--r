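cnvr,chrom,start,end,type,frequency,primer,pos_n,pos_confirmed,pos_rate_printed,neg_n,neg_confirmed,neg_rate_printed
43,1,284433601,284517960,loss,91.67,CGH1-1,11,11,1.0000,1,1,1.0000
43,1,284433601,284517960,loss,91.67,Gene2-2,11,11,1.0000,1,1,1.0000
47,1,296124751,296565810,loss,75,E1-2,9,3,0.3333,2,0,0.0000
72,10,22215991,23388810,loss,58.33,LD1-2,7,7,1.0000,5,3,0.6000
72,10,22215991,23388810,loss,58.33,LD1-3,7,7,1.0000,5,3,0.6000
105,11,62691810,62798160,gain,100,F1-2,12,12,1.0000,0,0,NA
105,11,62691810,62798160,gain,100,F1-3,12,12,1.0000,0,0,NA
108,11,62977560,62993310,loss,16.67,RD2B-4,2,2,1.0000,10,2,0.2000
114,11,70562251,71910060,both,66.67,J1-3,8,8,1.0000,4,1,0.2500
152,13,34207351,34233930,loss,91.67,CGH3-1,11,11,1.0000,1,1,1.0000
152,13,34207351,34233930,loss,91.67,Gene9-4,11,11,1.0000,1,1,1.0000
339,2,61350751,61455330,loss,16.67,R1-3,2,2,1.0000,10,7,0.7000
418,3,95980501,95990220,gain,100,CGH7-1,12,12,1.0000,0,0,NA
418,3,95980501,95990220,gain,100,CGH7-3,12,12,1.0000,0,0,NA
441,4,5501251,5544300,loss,16.67,D1,2,2,1.0000,10,6,0.6000
441,4,5501251,5544300,loss,16.67,D5,2,1,0.5000,10,0,0.0000
464,4,99641791,99708810,gain,58.33,F2,7,6,0.8571,5,2,0.4000
464,4,99641791,99708810,gain,58.33,F4,7,6,0.8571,5,1,0.2000
579,7,24621751,24759180,gain,58.33,RD14A-2,7,7,1.0000,5,3,0.6000
579,7,24621751,24759180,gain,58.33,RD14B-2,7,4,0.5714,5,0,0.0000
588,7,50301961,50677050,loss,16.67,D1-1,2,1,0.5000,11,0,0.0000
588,7,50301961,50677050,loss,16.67,D2-1,2,1,0.5000,11,0,0.0000
620,8,43301791,43891650,gain,16.67,CGH2-1,2,2,1.0000,10,0,0.0000
620,8,43301791,43891650,gain,16.67,kit6,2,2,1.0000,10,0,0.0000
659,9,29231131,29275230,gain,8.33,K5,1,1,1.0000,10,0,0.0000
734,X,91336681,91353210,loss,66.67,CGH6A-2,8,8,1.0000,4,2,0.5000
734,X,91336681,91353210,loss,66.67,CGH5B-1,8,8,1.0000,4,2,0.5000
736,X,92583421,92609190,loss,25,R2-2,3,3,1.0000,8,6,0.7500
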