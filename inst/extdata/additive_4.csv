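AABBCCDD,x
AABBCCDd,x * (1 + y)
AABBCCdd,x * (1 + y)^2
AABBCcDD,x * (1 + y)
AABBCcDd,x * (1 + y)^2
AABBCcdd,x * (1 + y)^3
AABBccDD,x * (1 + y)^2
AABBccDd,x * (1 + y)^3
AABBccdd,x * (1 + y)^4
AABbCCDD,x * (1 + y)
AABbCCDd,x * (1 + y)^2
AABbCCdd,x * (1 + y)^3
AABbCcDD,x * (1 + y)^2
AABbCcDd,x * (1 + y)^3
AABbCcdd,x * (1 + y)^4
AABbccDD,x * (1 + y)^3
AABbccDd,x * (1 + y)^4
AABbccdd,x * (1 + y)^5
AAbbCCDD,x * (1 + y)^2
AAbbCCDd,x * (1 + y)^3
AAbbCCdd,x * (1 + y)^4
AAbbCcDD,x * (1 + y)^3
AAbbCcDd,x * (1 + y)^4
AAbbCcdd,x * (1 + y)^5
AAbbccDD,x * (1 + y)^4
AAbbccDd,x * (1 + y)^5
AAbbccdd,x * (1 + y)^6
AaBBCCDD,x * (1 + y)
AaBBCCDd,x * (1 + y)^2
AaBBCCdd,x * (1 + y)^3
AaBBCcDD,x * (1 + y)^2
AaBBCcDd,x * (1 + y)^3
AaBBCcdd,x * (1 + y)^4
AaBBccDD,x * (1 + y)^3
AaBBccDd,x * (1 + y)^4
AaBBccdd,x * (1 + y)^5
AaBbCCDD,x * (1 + y)^2
AaBbCCDd,x * (1 + y)^3
AaBbCCdd,x * (1 + y)^4
AaBbCcDD,x * (1 + y)^3
AaBbCcDd,x * (1 + y)^4
AaBbCcdd,x * (1 + y)^5
AaBbccDD,x * (1 + y)^4
AaBbccDd,x * (1 + y)^5
AaBbccdd,x * (1 + y)^6
AabbCCDD,x * (1 + y)^3
AabbCCDd,x * (1 + y)^4
AabbCCdd,x * (1 + y)^5
AabbCcDD,x * (1 + y)^4
AabbCcDd,x * (1 + y)^5
AabbCcdd,x * (1 + y)^6
AabbccDD,x * (1 + y)^5
AabbccDd,x * (1 + y)^6
Aabbccdd,x * (1 + y)^7
aaBBCCDD,x * (1 + y)^2
aaBBCCDd,x * (1 + y)^3
aaBBCCdd,x * (1 + y)^4
aaBBCcDD,x * (1 + y)^3
aaBBCcDd,x * (1 + y)^4
aaBBCcdd,x * (1 + y)^5
aaBBccDD,x * (1 + y)^4
aaBBccDd,x * (1 + y)^5
aaBBccdd,x * (1 + y)^6
aaBbCCDD,x * (1 + y)^3
aaBbCCDd,x * (1 + y)^4
aaBbCCdd,x * (1 + y)^5
aaBbCcDD,x * (1 + y)^4
aaBbCcDd,x * (1 + y)^5
aaBbCcdd,x * (1 + y)^6
aaBbccDD,x * (1 + y)^5
aaBbccDd,x * (1 + y)^6
aaBbccdd,x * (1 + y)^7
aabbCCDD,x * (1 + y)^4
aabbCCDd,x * (1 + y)^5
aabbCCdd,x * (1 + y)^6
aabbCcDD,x * (1 + y)^5
aabbCcDd,x * (1 + y)^6
aabbCcdd,x * (1 + y)^7
aabbccDD,x * (1 + y)^6
aabbccDd,x * (1 + y)^7
aabbccdd,x * (1 + y)^8
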