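AABB,x
AABb,x
AAbb,x
AaBB,x
AaBb,x * (1 + y)
Aabb,x * (1 + y)
aaBB,x
aaBb,x * (1 + y)
aabb,x * (1 + y)
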