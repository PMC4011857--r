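fissure,bin,non_copd,gold_i,gold_ii,gold_iii,gold_iv
rof,"[0%, 20%]",0,0,0,0,0
rof,"(20%, 40%]",3,0,3,0,0
rof,"(40%, 60%]",5,3,3,2,5
rof,"(60%, 80%]",74,26,45,20,22
rof,"(80%, 90%]",82,35,52,22,22
rof,"(90%, 100%]",58,19,38,19,15
rhf,"[0%, 20%]",15,8,5,3,3
rhf,"(20%, 40%]",33,10,27,13,7
rhf,"(40%, 60%]",41,15,30,9,18
rhf,"(60%, 80%]",66,29,39,21,22
rhf,"(80%, 90%]",34,9,17,10,8
rhf,"(90%, 100%]",33,12,23,7,6
lof,"[0%, 20%]",1,0,1,0,0
lof,"(20%, 40%]",2,0,0,2,1
lof,"(40%, 60%]",10,3,7,2,4
lof,"(60%, 80%]",59,20,40,14,26
lof,"(80%, 90%]",88,38,59,28,25
lof,"(90%, 100%]",62,22,34,17,8
elf,"[0%, 20%]",0,0,0,0,0
elf,"(20%, 40%]",1,0,2,0,0
elf,"(40%, 60%]",13,3,6,3,3
elf,"(60%, 80%]",100,36,59,27,33
elf,"(80%, 90%]",82,38,60,24,26
elf,"(90%, 100%]",26,6,14,9,2
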