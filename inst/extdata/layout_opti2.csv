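id,label,row,col
1,q,1,1
2,f,1,2
3,u,1,3
4,m,1,4
5,c,1,5
6,k,1,6
7,z,2,1
8,o,2,2
9,t,2,3
10,h,2,4
11,b,2,5
12,j,2,6
13,_,3,1
14,s,3,2
15,r,3,3
16,e,3,4
17,a,3,5
18,_,3,6
19,x,4,1
20,i,4,2
21,n,4,3
22,d,4,4
23,w,4,5
24,<,4,6
25,g,5,1
26,l,5,2
27,p,5,3
28,y,5,4
29,v,5,5
30,_,5,6
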