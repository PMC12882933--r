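# kind: accuracy
# symmetric: TRUE
# provenance: published same-different study, Table 2 (symmetrized accuracy per letter pair); transcription checksum md5:2091e3cd6486081fa325009013157354
letter,a,b,c,d,e,f,g,h,i,j,k,l,m,n,o,p,q,r,s,t,u,v,w,x,y,z
a,0.981,1.0,0.905,0.959,0.963,0.981,1.0,1.0,0.938,1.0,0.943,0.979,0.94,1.0,0.962,0.98,1.0,0.94,1.0,1.0,0.979,1.0,0.98,0.959,1.0,0.962
b,1.0,0.945,0.945,0.979,0.98,0.961,0.866,0.917,0.983,0.979,0.96,0.808,0.979,1.0,0.962,0.979,0.981,1.0,0.961,1.0,1.0,0.982,0.982,0.961,1.0,0.981
c,0.905,0.945,0.976,0.98,1.0,1.0,1.0,0.979,0.981,0.963,0.98,0.981,1.0,1.0,1.0,1.0,0.98,1.0,1.0,1.0,1.0,0.981,0.98,0.982,0.961,0.96
d,0.959,0.979,0.98,0.959,0.9,0.957,0.96,0.9,1.0,1.0,1.0,1.0,1.0,0.981,0.943,1.0,1.0,0.981,1.0,0.981,1.0,0.981,0.98,1.0,0.98,1.0
e,0.963,0.98,1.0,0.9,0.948,1.0,1.0,0.96,1.0,0.981,1.0,0.963,1.0,1.0,1.0,1.0,1.0,0.979,0.961,1.0,1.0,0.961,0.98,0.982,1.0,1.0
f,0.981,0.961,1.0,0.957,1.0,0.913,0.824,0.901,0.981,0.921,1.0,0.96,0.979,1.0,0.981,0.96,0.96,1.0,0.961,0.924,1.0,1.0,0.982,0.982,1.0,0.982
g,1.0,0.866,1.0,0.96,1.0,0.824,0.917,0.942,1.0,0.944,1.0,1.0,1.0,1.0,1.0,0.963,0.94,0.959,0.96,1.0,0.94,0.959,0.945,1.0,0.979,1.0
h,1.0,0.917,0.979,0.9,0.96,0.901,0.942,0.948,1.0,0.914,1.0,1.0,1.0,1.0,0.982,1.0,0.962,0.882,1.0,1.0,1.0,0.922,0.959,1.0,0.979,1.0
i,0.938,0.983,0.981,1.0,1.0,0.981,1.0,1.0,0.924,0.745,1.0,0.982,1.0,1.0,1.0,0.982,0.979,1.0,0.92,0.98,0.982,1.0,0.98,0.961,0.961,1.0
j,1.0,0.979,0.963,1.0,0.981,0.921,0.944,0.914,0.745,0.939,0.98,0.982,0.961,1.0,0.96,0.962,1.0,1.0,0.979,0.941,0.982,0.98,0.96,0.98,1.0,1.0
k,0.943,0.96,0.98,1.0,1.0,1.0,1.0,1.0,1.0,0.98,0.939,0.98,0.94,0.98,0.961,0.981,1.0,1.0,1.0,1.0,0.867,1.0,1.0,0.941,0.982,0.98
l,0.979,0.808,0.981,1.0,0.963,0.96,1.0,1.0,0.982,0.982,0.98,0.945,1.0,1.0,1.0,0.94,0.94,0.882,0.981,0.926,0.96,0.885,0.98,0.981,0.98,1.0
m,0.94,0.979,1.0,1.0,1.0,0.979,1.0,1.0,1.0,0.961,0.94,1.0,0.932,0.979,1.0,0.942,0.979,0.945,1.0,1.0,0.9,0.959,0.981,0.778,0.963,1.0
n,1.0,1.0,1.0,0.981,1.0,1.0,1.0,1.0,1.0,1.0,0.98,1.0,0.979,0.882,0.701,0.98,0.96,0.981,0.96,0.981,1.0,1.0,0.904,0.981,0.704,0.734
o,0.962,0.962,1.0,0.943,1.0,0.981,1.0,0.982,1.0,0.96,0.961,1.0,1.0,0.701,0.917,1.0,1.0,0.982,0.98,0.979,0.98,1.0,0.963,1.0,0.979,0.765
p,0.98,0.979,1.0,1.0,1.0,0.96,0.963,1.0,0.982,0.962,0.981,0.94,0.942,0.98,1.0,0.889,0.88,0.877,0.908,0.923,0.981,0.96,0.938,1.0,0.94,1.0
q,1.0,0.981,0.98,1.0,1.0,0.96,0.94,0.962,0.979,1.0,1.0,0.94,0.979,0.96,1.0,0.88,0.893,0.863,0.94,0.824,1.0,0.937,0.896,1.0,0.938,0.982
r,0.94,1.0,1.0,0.981,0.979,1.0,0.959,0.882,1.0,1.0,1.0,0.882,0.945,0.981,0.982,0.877,0.863,0.888,1.0,0.918,0.98,0.883,0.86,1.0,0.963,0.919
s,1.0,0.961,1.0,1.0,0.961,0.961,0.96,1.0,0.92,0.979,1.0,0.981,1.0,0.96,0.98,0.908,0.94,1.0,0.946,0.711,0.981,0.979,0.959,0.965,0.981,0.981
t,1.0,1.0,1.0,0.981,1.0,0.924,1.0,1.0,0.98,0.941,1.0,0.926,1.0,0.981,0.979,0.923,0.824,0.918,0.711,0.907,0.981,0.981,0.845,0.98,1.0,1.0
u,0.979,1.0,1.0,1.0,1.0,1.0,0.94,1.0,0.982,0.982,0.867,0.96,0.9,1.0,0.98,0.981,1.0,0.98,0.981,0.981,0.945,0.981,0.981,0.869,0.982,0.96
v,1.0,0.982,0.981,0.981,0.961,1.0,0.959,0.922,1.0,0.98,1.0,0.885,0.959,1.0,1.0,0.96,0.937,0.883,0.979,0.981,0.981,0.943,1.0,1.0,0.96,1.0
w,0.98,0.982,0.98,0.98,0.98,0.982,0.945,0.959,0.98,0.96,1.0,0.98,0.981,0.904,0.963,0.938,0.896,0.86,0.959,0.845,0.981,1.0,0.91,1.0,0.98,0.94
x,0.959,0.961,0.982,1.0,0.982,0.982,1.0,1.0,0.961,0.98,0.941,0.981,0.778,0.981,1.0,1.0,1.0,1.0,0.965,0.98,0.869,1.0,1.0,0.936,0.959,0.979
y,1.0,1.0,0.961,0.98,1.0,1.0,0.979,0.979,0.961,1.0,0.982,0.98,0.963,0.704,0.979,0.94,0.938,0.963,0.981,1.0,0.982,0.96,0.98,0.959,0.879,0.783
z,0.962,0.981,0.96,1.0,1.0,0.982,1.0,1.0,1.0,1.0,0.98,1.0,1.0,0.734,0.765,1.0,0.982,0.919,0.981,1.0,0.96,1.0,0.94,0.979,0.783,0.897
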