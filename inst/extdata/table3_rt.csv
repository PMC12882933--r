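# kind: dissimilarity
# symmetric: TRUE
# provenance: published same-different study, Table 3 (reciprocal symmetrized median adjusted RT); transcription checksum md5:27c41aec5fce44e4be8b45c367bdd62b
letter,a,b,c,d,e,f,g,h,i,j,k,l,m,n,o,p,q,r,s,t,u,v,w,x,y,z
a,1.046,1.054,0.907,1.029,1.047,0.955,1.002,1.038,0.962,1.045,0.998,0.982,1.005,1.036,1.033,1.054,0.999,1.059,1.014,0.989,1.006,1.048,1.03,1.056,1.043,1.053
b,1.054,1.031,0.977,0.992,1.006,0.977,0.993,0.978,0.996,0.995,1.051,0.956,1.082,0.998,1.018,1.002,1.029,0.998,0.997,1.01,1.072,1.045,1.029,1.029,1.029,1.023
c,0.907,0.977,1.094,0.971,1.055,1.039,1.043,1.035,1.033,1.013,1.021,1.04,1.06,1.041,1.057,1.047,0.977,1.013,1.072,1.032,1.021,1.024,1.02,1.056,1.092,1.037
d,1.029,0.992,0.971,1.033,0.955,0.907,1.009,0.98,1.013,0.953,0.965,0.996,1.028,1.033,1.044,1.042,1.057,1.013,1.031,1.0,1.08,1.027,0.998,1.005,1.013,1.035
e,1.047,1.006,1.055,0.955,1.04,1.011,0.961,0.987,0.945,1.005,1.036,1.057,1.034,1.054,0.972,1.072,1.018,1.002,1.03,1.038,1.06,1.07,0.971,1.031,1.098,1.02
f,0.955,0.977,1.039,0.907,1.011,1.009,0.92,0.937,1.004,0.919,0.992,0.99,1.049,1.001,1.045,1.059,0.919,0.991,1.028,1.03,1.019,1.046,1.004,1.032,1.019,1.018
g,1.002,0.993,1.043,1.009,0.961,0.92,1.036,0.941,1.025,0.987,1.078,0.986,1.025,1.033,1.007,0.956,0.917,0.969,1.022,1.004,1.02,1.037,1.03,1.026,1.021,1.009
h,1.038,0.978,1.035,0.98,0.987,0.937,0.941,1.013,0.999,0.883,1.055,1.007,1.061,0.999,1.01,1.009,1.04,0.989,0.989,1.017,1.042,1.001,0.959,1.009,1.036,0.995
i,0.962,0.996,1.033,1.013,0.945,1.004,1.025,0.999,0.99,0.901,0.99,1.056,1.006,1.047,1.025,0.993,1.05,1.014,0.965,1.018,1.05,1.057,1.04,1.028,1.033,1.0
j,1.045,0.995,1.013,0.953,1.005,0.919,0.987,0.883,0.901,0.991,1.067,1.023,1.103,0.99,1.016,1.086,1.027,1.006,1.006,1.021,1.021,1.015,0.991,1.042,1.026,1.03
k,0.998,1.051,1.021,0.965,1.036,0.992,1.078,1.055,0.99,1.067,1.016,1.018,0.942,0.96,0.969,0.997,1.045,0.989,1.009,1.04,0.913,1.02,0.961,0.998,1.004,1.009
l,0.982,0.956,1.04,0.996,1.057,0.99,0.986,1.007,1.056,1.023,1.018,1.027,0.992,1.05,1.033,0.945,1.018,0.938,1.024,1.002,0.969,0.983,1.0,1.002,1.006,1.018
m,1.005,1.082,1.06,1.028,1.034,1.049,1.025,1.061,1.006,1.103,0.942,0.992,1.014,1.004,0.999,1.004,1.025,1.01,1.007,1.007,0.912,1.033,1.027,0.933,0.968,1.035
n,1.036,0.998,1.041,1.033,1.054,1.001,1.033,0.999,1.047,0.99,0.96,1.05,1.004,0.964,0.851,0.953,0.978,0.962,0.997,0.922,0.966,1.011,0.98,0.963,0.934,0.867
o,1.033,1.018,1.057,1.044,0.972,1.045,1.007,1.01,1.025,1.016,0.969,1.033,0.999,0.851,0.981,1.008,0.963,0.984,1.013,1.017,0.99,1.028,0.941,0.969,0.943,0.776
p,1.054,1.002,1.047,1.042,1.072,1.059,0.956,1.009,0.993,1.086,0.997,0.945,1.004,0.953,1.008,0.974,0.875,0.975,0.958,0.928,1.053,0.934,0.976,0.96,0.986,1.006
q,0.999,1.029,0.977,1.057,1.018,0.919,0.917,1.04,1.05,1.027,1.045,1.018,1.025,0.978,0.963,0.875,0.948,0.867,0.938,0.947,1.025,1.017,0.927,0.97,0.971,0.956
r,1.059,0.998,1.013,1.013,1.002,0.991,0.969,0.989,1.014,1.006,0.989,0.938,1.01,0.962,0.984,0.975,0.867,0.976,1.015,0.928,1.013,0.906,0.847,1.044,0.963,0.953
s,1.014,0.997,1.072,1.031,1.03,1.028,1.022,0.989,0.965,1.006,1.009,1.024,1.007,0.997,1.013,0.958,0.938,1.015,0.97,0.893,0.993,1.032,0.939,1.047,1.016,1.034
t,0.989,1.01,1.032,1.0,1.038,1.03,1.004,1.017,1.018,1.021,1.04,1.002,1.007,0.922,1.017,0.928,0.947,0.928,0.893,0.978,0.98,0.978,0.953,1.045,1.002,1.024
u,1.006,1.072,1.021,1.08,1.06,1.019,1.02,1.042,1.05,1.021,0.913,0.969,0.912,0.966,0.99,1.053,1.025,1.013,0.993,0.98,1.004,0.95,1.003,0.871,1.021,0.993
v,1.048,1.045,1.024,1.027,1.07,1.046,1.037,1.001,1.057,1.015,1.02,0.983,1.033,1.011,1.028,0.934,1.017,0.906,1.032,0.978,0.95,1.001,0.951,0.991,0.976,0.996
w,1.03,1.029,1.02,0.998,0.971,1.004,1.03,0.959,1.04,0.991,0.961,1.0,1.027,0.98,0.941,0.976,0.927,0.847,0.939,0.953,1.003,0.951,0.931,1.013,0.945,0.912
x,1.056,1.029,1.056,1.005,1.031,1.032,1.026,1.009,1.028,1.042,0.998,1.002,0.933,0.963,0.969,0.96,0.97,1.044,1.047,1.045,0.871,0.991,1.013,1.031,0.9,0.917
y,1.043,1.029,1.092,1.013,1.098,1.019,1.021,1.036,1.033,1.026,1.004,1.006,0.968,0.934,0.943,0.986,0.971,0.963,1.016,1.002,1.021,0.976,0.945,0.9,0.957,0.896
z,1.053,1.023,1.037,1.035,1.02,1.018,1.009,0.995,1.0,1.03,1.009,1.018,1.035,0.867,0.776,1.006,0.956,0.953,1.034,1.024,0.993,0.996,0.912,0.917,0.896,0.958
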