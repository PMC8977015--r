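AABBCCDD,x
AABBCCDd,x
AABBCCdd,x
AABBCcDD,x
AABBCcDd,x
AABBCcdd,x
AABBccDD,x
AABBccDd,x
AABBccdd,x
AABbCCDD,x
AABbCCDd,x
AABbCCdd,x
AABbCcDD,x
AABbCcDd,x
AABbCcdd,x
AABbccDD,x
AABbccDd,x
AABbccdd,x
AAbbCCDD,x
AAbbCCDd,x
AAbbCCdd,x
AAbbCcDD,x
AAbbCcDd,x
AAbbCcdd,x
AAbbccDD,x
AAbbccDd,x
AAbbccdd,x
AaBBCCDD,x
AaBBCCDd,x
AaBBCCdd,x
AaBBCcDD,x
AaBBCcDd,x
AaBBCcdd,x
AaBBccDD,x
AaBBccDd,x
AaBBccdd,x
AaBbCCDD,x
AaBbCCDd,x
AaBbCCdd,x
AaBbCcDD,x
AaBbCcDd,x * (1 + y)
AaBbCcdd,x * (1 + y)^2
AaBbccDD,x
AaBbccDd,x * (1 + y)^2
AaBbccdd,x * (1 + y)^4
AabbCCDD,x
AabbCCDd,x
AabbCCdd,x
AabbCcDD,x
AabbCcDd,x * (1 + y)^2
AabbCcdd,x * (1 + y)^4
AabbccDD,x
AabbccDd,x * (1 + y)^4
Aabbccdd,x * (1 + y)^8
aaBBCCDD,x
aaBBCCDd,x
aaBBCCdd,x
aaBBCcDD,x
aaBBCcDd,x
aaBBCcdd,x
aaBBccDD,x
aaBBccDd,x
aaBBccdd,x
aaBbCCDD,x
aaBbCCDd,x
aaBbCCdd,x
aaBbCcDD,x
aaBbCcDd,x * (1 + y)^2
aaBbCcdd,x * (1 + y)^4
aaBbccDD,x
aaBbccDd,x * (1 + y)^4
aaBbccdd,x * (1 + y)^8
aabbCCDD,x
aabbCCDd,x
aabbCCdd,x
aabbCcDD,x
aabbCcDd,x * (1 + y)^4
aabbCcdd,x * (1 + y)^8
aabbccDD,x
aabbccDd,x * (1 + y)^8
aabbccdd,x * (1 + y)^16
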