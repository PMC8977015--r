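AABB,x
AABb,x * (1 + y)
AAbb,x * (1 + y)^2
AaBB,x * (1 + y)
AaBb,x * (1 + y)^2
Aabb,x * (1 + y)^3
aaBB,x * (1 + y)^2
aaBb,x * (1 + y)^3
aabb,x * (1 + y)^4
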