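split,parameter,group1,n1,mean1,sd1,group2,n2,mean2,sd2,published_p
grade,ADCmean,III,11,136.90,29.88,IV,45,137.70,32.68,0.9398
grade,ADCmin,III,11,61.29,6.17,IV,45,34.14,4.23,0.0040
grade,ADCmax,III,11,231.90,49.08,IV,45,300.00,54.75,0.0001
grade,ADCp10,III,11,108.60,8.87,IV,45,92.40,2.56,0.0194
grade,ADCp25,III,11,121.10,32.91,IV,45,106.80,21.48,0.0820
grade,ADCp75,III,11,153.00,30.24,IV,45,164.30,49.78,0.9639
grade,ADCp90,III,11,166.70,26.29,IV,45,191.60,53.57,0.2507
grade,ADCmedian,III,11,135.70,33.96,IV,45,131.60,35.84,0.2772
grade,ADCmode,III,11,136.50,40.47,IV,45,129.00,57.81,0.1032
grade,ADCsd,III,11,23.55,5.42,IV,45,40.38,16.25,<0.0001
grade,Kurtosis,III,11,3.97,1.67,IV,45,5.18,4.40,0.7759
grade,Skewness,III,11,0.07,0.79,IV,45,0.88,0.94,0.0108
grade,Entropy,III,11,4.77,0.39,IV,45,4.72,0.54,0.7561
grade,ki67,III,11,15.20,14.33,IV,45,28.38,17.77,0.0012
mgmt,ADCmean,methylated,21,133.50,31.62,unmethylated,29,139.30,31.93,0.5258
mgmt,ADCmin,methylated,21,42.16,29.67,unmethylated,29,35.57,28.81,0.4208
mgmt,ADCmax,methylated,21,277.70,59.54,unmethylated,29,291.90,61.92,0.3074
mgmt,ADCp10,methylated,21,94.83,22.31,unmethylated,29,95.08,20.66,0.7442
mgmt,ADCp25,methylated,21,106.90,25.01,unmethylated,29,110.70,25.06,0.5951
mgmt,ADCp75,methylated,21,157.40,46.59,unmethylated,29,164.20,46.06,0.9650
mgmt,ADCp90,methylated,21,183.70,52.29,unmethylated,29,189.00,50.06,0.9070
mgmt,ADCmedian,methylated,21,125.40,29.87,unmethylated,29,135.20,36.59,0.7739
mgmt,ADCmode,methylated,21,119.70,46.31,unmethylated,29,134.70,58.25,0.5424
mgmt,ADCsd,methylated,21,35.99,15.59,unmethylated,29,37.93,16.87,0.6808
mgmt,Kurtosis,methylated,21,4.36,2.41,unmethylated,29,5.01,3.80,0.9534
mgmt,Skewness,methylated,21,0.87,0.68,unmethylated,29,0.58,1.02,0.2737
mgmt,Entropy,methylated,21,4.79,0.52,unmethylated,29,4.84,0.45,0.9789
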