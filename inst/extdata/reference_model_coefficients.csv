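model,term,estimate,se,z,p,ci_low,ci_high
I,ExpEco,5.85,1.54,3.81,0.001,2.84,8.86
I,ExpSoc,1.79,1.31,1.37,0.171,-0.77,4.36
I,LnPop,-2.18,0.27,-8.07,0.001,-2.71,-1.65
I,LnGDP,1.89,0.31,6.11,0.001,1.29,2.50
I,const,67.06,3.39,19.79,0.001,60.42,73.71
II,GiniEco,-11.69,3.24,-3.61,0.001,-18.04,-5.33
II,GiniSoc,-0.54,3.04,-0.18,0.859,-6.50,5.42
II,LnPop,-2.14,0.28,-7.75,0.001,-2.68,-1.60
II,LnGDP,2.61,0.24,10.75,0.001,2.14,3.09
II,const,64.50,3.07,21.04,0.001,58.50,70.51
III,ExpEco,3.84,1.82,2.11,0.035,0.28,7.41
III,ExpSoc,2.23,1.32,1.69,0.091,-0.36,4.82
III,GiniEco,-9.95,3.36,-2.96,0.003,-16.54,-3.36
III,GiniSoc,3.03,3.22,0.94,0.346,-3.28,9.35
III,LnPop,-2.07,0.27,-7.64,0.001,-2.61,-1.54
III,LnGDP,2.01,0.32,6.34,0.001,1.39,2.64
III,const,66.86,3.21,20.82,0.001,60.56,73.15
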