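condition,stratum,NEM,IEM,EGJ_OO,Achalasia,Other
ftc,irp_normal,53,24,0,0,8
ftc,irp_elevated,0,0,21,18,0
nontc,irp_normal,38,22,14,2,9
nontc,irp_elevated,1,1,20,17,0
tc1,irp_normal,52,22,0,0,11
tc1,irp_elevated,7,0,14,17,1
tc5,irp_normal,52,21,3,1,8
tc5,irp_elevated,6,1,14,18,0
tc10,irp_normal,55,14,7,1,8
tc10,irp_elevated,6,1,15,17,0
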