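compound,class,rt_min,ri,mean_Egypt,sd_Egypt,mean_Morocco,sd_Morocco,mean_Greece,sd_Greece,mean_Spain,sd_Spain,mean_Nectar,sd_Nectar,f_value,sig_code
1-Octanol,alcohol,18.92,1069,0,0,0,0,0,0,0,0,0.003,0.005,4.21,**
1-Nonanol,alcohol,21.04,1170,0,0,0,0,0,0,0,0,0.01,0.01,24.27,***
2-Methylbutanal,aldehyde,6.79,<800,0.07,0.09,0,0,0,0,0,0,0,0,5.11,**
Furfural,aldehyde,13.25,837,0.13,0.17,0.14,0.22,0.01,0.01,0.004,0.01,0.02,0.02,3.22,*
Benzaldehyde,aldehyde,16.75,978,0,0,0.04,0.05,0.04,0.02,0.004,0.01,0.07,0.09,3.65,*
Octanal,aldehyde,17.45,1005,0,0,0.01,0.02,0.02,0.03,0,0,0.01,0.01,1.58,ns
Benzeneacetaldehyde,aldehyde,18.58,1059,0,0,0.10,0.09,0.10,0.11,0.003,0.01,0.46,0.50,5.88,**
Nonanal,aldehyde,19.64,1107,0,0,0.09,0.05,0.15,0.11,0.03,0.06,0,0,7.58,***
"Lilac aldehyde (isomer I, A)",aldehyde,20.57,1147,0.13,0.23,0.06,0.09,0.05,0.14,0.10,0.09,0,0,0.89,ns
"Lilac aldehyde (isomer II, B)",aldehyde,20.63,1149,0.06,0.08,0.06,0.11,0.24,0.22,0.06,0.06,0.04,0.06,3.89,**
"Lilac aldehyde (isomer III, C)",aldehyde,20.76,1156,0.14,0.07,0.27,0.09,0.31,0.35,0.09,0.08,0,0,2.75,*
"Lilac aldehyde (isomer IV, D)",aldehyde,21.17,1176,0,0,0,0,0,0,0.06,0.02,0,0,49.19,***
Decanal,aldehyde,21.77,1209,0,0,0,0,0.09,0.13,0,0,0.03,0.02,3.48,*
"alpha,4-Dimethyl-3-cyclohexene-1-acetaldehyde",aldehyde,22.31,1234,0.05,0.07,0.07,0.04,0.003,0.01,0.06,0.04,0.003,0.005,6.41,***
Heptane,hydrocarbon,9.49,<800,0.09,0.05,0.05,0.06,0,0,0.04,0.06,0,0,7.92,***
Octane,hydrocarbon,12.26,800,0.01,0.02,0.01,0.02,0.03,0.02,0.01,0.01,0.04,0.02,3.18,*
Nonane,hydrocarbon,14.94,900,0,0,0,0,0.02,0.03,0,0,0.001,0.01,1.56,ns
Delta-3-carene,hydrocarbon,17.94,1024,0,0,0,0,0,0,0,0,0.007,0.005,16.84,***
Undecane,hydrocarbon,19.59,1099,0,0,0,0,0,0,0,0,0.007,0.005,16.84,***
Dill ether,ether,21.72,1203,0.11,0.08,0.13,0.05,0,0,0.07,0.03,0.003,0.005,22.42,***
Ethyl hexanoate,ester,17.25,993,0,0,0,0,0,0,0,0,0.003,0.005,4.21,**
Ethyl malonate,ester,18.67,1044,0,0,0,0,0,0,0,0,0.003,0.005,4.21,**
Ethyl heptanoate,ester,19.44,1092,0,0,0,0,0,0,0,0,0.007,0.005,16.84,***
Ethyl octanoate,ester,21.36,1191,0,0,0.01,0.01,0.03,0.02,0.003,0.009,0.03,0.02,7.94,***
Ethyl nonanoate,ester,23.26,1290,0.03,0.05,0.01,0.02,0.04,0.03,0.02,0.02,0.07,0.05,2.89,*
Methyl anthranilate,ester,24.74,1366,0.03,0.05,0,0,0.02,0.03,0,0,0,0,2.06,ns
Ethyl decanoate,ester,25.05,1389,0.04,0.09,0,0,0.02,0.02,0.09,0.02,0.04,0.01,1.02,ns
Ethyl dodecanoate,ester,28.42,1588,0,0,0,0,0.003,0.004,0,0,0.01,0.00,12.42,***
Ethyl hexadecanoate,ester,34.94,1990,0,0,0,0,0.002,0.004,0,0,0,0,1.29,ns
6-Methyl-5-hepten-2-one,ketone,17.06,986,0,0,0,0,0.001,0.002,0,0,0,0,2.85,*
beta-Damascenone,ketone,25.37,1401,0,0,0,0,0.003,0.06,0,0,0.003,0.005,1.75,ns
Benzeneethanol,phenolic,20.20,1129,0,0,0,0,0,0,0,0,0.07,0.09,7.16,***
Benzeneacetonitrile,phenolic,20.71,1154,0,0,0,0,0,0,0,0,0.04,0.05,7.35,***
"3,4,5-Trimethylphenol",phenolic,24.10,1330,0,0,0,0,0.003,0.005,0,0,0.002,0.004,1.16,ns
alpha-Pinene,terpene,16.18,949,0,0,0,0,0.01,0.09,0,0,0.01,0.004,3.38,*
Herboxide isomer II,terpene,17.55,1007,0.05,0.05,0.10,0.13,0.01,0.01,0.08,0.06,0.003,0.01,4.92,**
Para-cymene,terpene,18.13,1038,0,0,0.03,0.05,0.03,0.03,0.03,0.05,0,0,2.24,ns
dL-Limonene,terpene,18.25,1044,0.01,0.02,0.01,0.01,0.002,0.003,0,0,0,0,0.86,ns
cis-Linalool oxide,terpene,19.11,1077,0.08,0.08,0.11,0.04,0.02,0.01,0.04,0.02,0.003,0.01,9.02,***
Linalool,terpene,19.54,1103,0.04,0.05,0.02,0.02,0.07,0.03,0.06,0.02,0.02,0.03,4.29,**
Hotrienol,terpene,19.63,1104,0,0,0.01,0.02,0,0,0.02,0.03,0.03,0.08,1.47,ns
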