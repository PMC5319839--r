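from,to,weight
t,h,3.56
h,e,3.07
i,n,2.43
e,r,2.05
a,n,1.99
r,e,1.85
o,n,1.76
a,t,1.49
e,n,1.45
n,d,1.35
t,i,1.34
e,s,1.34
o,r,1.28
t,e,1.20
o,f,1.17
e,d,1.17
i,s,1.13
i,t,1.12
a,l,1.09
a,r,1.07
s,t,1.05
t,o,1.05
n,t,1.04
n,g,0.95
s,e,0.93
h,a,0.93
a,s,0.87
o,u,0.87
i,o,0.83
l,e,0.83
v,e,0.83
c,o,0.79
m,e,0.79
d,e,0.76
h,i,0.76
r,i,0.73
r,o,0.73
i,c,0.70
n,e,0.69
e,a,0.69
r,a,0.69
c,e,0.65
l,i,0.62
c,h,0.60
l,l,0.58
b,e,0.58
m,a,0.57
s,i,0.55
o,m,0.55
u,r,0.54
e,_,3.20
s,_,2.10
d,_,1.80
t,_,1.60
n,_,1.40
y,_,1.05
_,t,2.70
_,a,2.00
_,i,1.50
_,s,1.45
_,o,1.40
_,w,1.25
_,b,0.95
_,h,0.90
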