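risk,sex,dalys_1990,dalys_2019,dalys_pct_change,asdr_1990,asdr_2019,asdr_pct_change,paf_1990,paf_2019
all_risk_factors,Male,42898.31,67474,57.29,2226.75,1711.58,-23.14,48.39,47.22
all_risk_factors,Female,22580.18,37563.38,66.36,1037.14,866.87,-16.42,32.62,33.55
all_risk_factors,Both,65478.5,105037.38,60.42,1587.05,1262.68,-20.44,41.51,41.23
air_pollution,Male,4291.25,6253.19,45.72,219.38,157.86,-28.04,4.76,4.35
air_pollution,Female,1463.54,2698.78,84.4,67.37,61.97,-8.02,2.12,2.4
air_pollution,Both,5754.8,8951.97,55.56,138.76,107.36,-22.63,3.63,3.5
other_environmental_risks,Male,925.51,1299.59,40.42,47.76,32.99,-30.92,1.04,0.91
other_environmental_risks,Female,287.99,585.89,103.44,13.29,13.44,1.14,0.42,0.52
other_environmental_risks,Both,1213.5,1885.48,55.37,29.43,22.66,-22.98,0.77,0.74
tobacco,Male,32710,47632.1,45.62,1707.61,1207.72,-29.27,37.11,33.31
tobacco,Female,7552.81,11691.47,54.8,350.69,267.84,-23.62,11.03,10.37
tobacco,Both,40262.81,59323.57,47.34,983.22,711.71,-27.61,25.71,23.24
alcohol_use,Male,6073.94,10470.27,72.38,300.94,259.87,-13.65,6.54,7.17
alcohol_use,Female,1885.77,2521.1,33.69,86.99,58.25,-33.04,2.74,2.26
alcohol_use,Both,7959.7,12991.38,63.21,189.37,155.19,-18.05,4.95,5.07
drug_use,Male,624.56,966.06,54.68,31.29,24.52,-21.66,0.68,0.68
drug_use,Female,411.46,645.12,56.79,18.97,14.76,-22.19,0.6,0.57
drug_use,Both,1036.02,1611.18,55.52,24.82,19.36,-21.98,0.65,0.63
high_fasting_plasma_glucose,Male,1798.2,4599.74,155.8,100.9,120.41,19.35,2.19,3.32
high_fasting_plasma_glucose,Female,1489.43,3981.04,167.29,70.24,90.98,29.54,2.21,3.52
high_fasting_plasma_glucose,Both,3287.64,8580.78,161,83.74,104.24,24.49,2.19,3.41
high_body_mass_index,Male,2236.51,6011.22,168.78,113.66,150.73,32.62,2.47,4.16
high_body_mass_index,Female,2249.66,5164.09,129.55,105.02,117.76,12.13,3.3,4.56
high_body_mass_index,Both,4486.18,11175.31,149.11,109.89,133.93,21.88,2.87,4.37
dietary_risks,Male,5491.49,8347.44,52.01,286.43,213.16,-25.58,6.22,5.88
dietary_risks,Female,3877.51,5603.85,44.52,180.01,129.18,-28.24,5.66,5
dietary_risks,Both,9369,13951.29,48.91,229.56,168.77,-26.48,6,5.51
low_physical_activity,Male,205.58,478.9,132.95,12.89,13.26,2.91,0.28,0.37
low_physical_activity,Female,402.34,723.76,79.89,19.34,16.58,-14.28,0.61,0.64
low_physical_activity,Both,607.92,1202.65,97.83,16.35,14.98,-8.37,0.43,0.49
occupational_risks,Male,3760.3,5523.05,46.88,206.29,144.38,-30.01,4.49,3.98
occupational_risks,Female,765.15,1441.73,88.42,35.24,33.1,-6.06,1.11,1.28
occupational_risks,Both,4525.45,6964.78,53.9,112.44,84.42,-24.92,2.94,2.76
unsafe_sex,Female,6176.25,8955.01,44.99,275.05,210.64,-23.42,8.65,8.15
unsafe_sex,Both,6176.25,8955.01,44.99,139.98,107.2,-23.42,3.66,3.5
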