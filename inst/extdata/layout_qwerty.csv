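id,label,row,col
1,q,1,1
2,w,1,2
3,e,1,3
4,r,1,4
5,t,1,5
6,y,1,6
7,u,1,7
8,i,1,8
9,o,1,9
10,p,1,10
11,a,2,1
12,s,2,2
13,d,2,3
14,f,2,4
15,g,2,5
16,h,2,6
17,j,2,7
18,k,2,8
19,l,2,9
20,<,2,10
21,z,3,1
22,x,3,2
23,c,3,3
24,v,3,4
25,b,3,5
26,n,3,6
27,m,3,7
28,",",3,8
29,.,3,9
30,_,3,10
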