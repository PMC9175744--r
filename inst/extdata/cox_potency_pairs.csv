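compound,target,kind,pic50,ic50_um
aspirin,PTGS1,predicted,3.787,163.305
SC-560,PTGS1,predicted,8.098,0.008
celecoxib,PTGS2,predicted,7.017,0.096
valdecoxib,PTGS2,predicted,6.552,0.281
NS-398,PTGS2,predicted,5.242,5.729
aspirin,PTGS1,actual,4.557,27.750
SC-560,PTGS1,actual,8.046,0.009
celecoxib,PTGS2,actual,7.398,0.04
valdecoxib,PTGS2,actual,8.301,0.005
NS-398,PTGS2,actual,5.420,3.800
salvianolic_acid_B,PTGS1,predicted,6.079,0.834
salvianolic_acid_B,PTGS2,predicted,5.490,3.236
rosmarinic_acid,PTGS1,predicted,5.946,1.132
rosmarinic_acid,PTGS2,predicted,4.743,18.071
lithospermic_acid,PTGS1,predicted,6.079,0.834
lithospermic_acid,PTGS2,predicted,5.404,3.945
salvianolic_acid_D,PTGS1,predicted,6.568,0.270
salvianolic_acid_D,PTGS2,predicted,5.501,3.155
salvianolic_acid_Y,PTGS1,predicted,6.079,0.834
salvianolic_acid_Y,PTGS2,predicted,5.490,3.236
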