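id,label,row,col
1,a,1,1
2,b,1,2
3,c,1,3
4,d,1,4
5,e,1,5
6,f,1,6
7,g,1,7
8,h,1,8
9,i,1,9
10,j,1,10
11,k,2,1
12,l,2,2
13,m,2,3
14,n,2,4
15,o,2,5
16,p,2,6
17,q,2,7
18,r,2,8
19,s,2,9
20,<,2,10
21,t,3,1
22,u,3,2
23,v,3,3
24,w,3,4
25,x,3,5
26,y,3,6
27,z,3,7
28,",",3,8
29,.,3,9
30,_,3,10
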