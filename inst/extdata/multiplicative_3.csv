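AABBCC,x
AABBCc,x
AABBcc,x
AABbCC,x
AABbCc,x
AABbcc,x
AAbbCC,x
AAbbCc,x
AAbbcc,x
AaBBCC,x
AaBBCc,x
AaBBcc,x
AaBbCC,x
AaBbCc,x * (1 + y)
AaBbcc,x * (1 + y)^2
AabbCC,x
AabbCc,x * (1 + y)^2
Aabbcc,x * (1 + y)^4
aaBBCC,x
aaBBCc,x
aaBBcc,x
aaBbCC,x
aaBbCc,x * (1 + y)^2
aaBbcc,x * (1 + y)^4
aabbCC,x
aabbCc,x * (1 + y)^4
aabbcc,x * (1 + y)^8
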