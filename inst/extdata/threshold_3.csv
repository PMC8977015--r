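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
AaBbcc,x * (1 + y)
AabbCC,x
AabbCc,x * (1 + y)
Aabbcc,x * (1 + y)
aaBBCC,x
aaBBCc,x
aaBBcc,x
aaBbCC,x
aaBbCc,x * (1 + y)
aaBbcc,x * (1 + y)
aabbCC,x
aabbCc,x * (1 + y)
aabbcc,x * (1 + y)
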