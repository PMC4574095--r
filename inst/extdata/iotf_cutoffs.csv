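sex,age_years,bmi_overweight,bmi_obese
male,2,18.41,20.09
male,2.5,18.13,19.80
male,3,17.89,19.57
male,3.5,17.69,19.39
male,4,17.55,19.29
male,4.5,17.47,19.26
male,5,17.42,19.30
male,5.5,17.45,19.47
male,6,17.55,19.78
male,6.5,17.71,20.23
male,7,17.92,20.63
male,7.5,18.16,21.09
male,8,18.44,21.60
male,8.5,18.76,22.17
male,9,19.10,22.77
male,9.5,19.46,23.39
male,10,19.84,24.00
male,10.5,20.20,24.57
male,11,20.55,25.10
male,11.5,20.89,25.58
male,12,21.22,26.02
male,12.5,21.56,26.43
male,13,21.91,26.84
male,13.5,22.27,27.25
male,14,22.62,27.63
male,14.5,22.96,27.98
male,15,23.29,28.30
male,15.5,23.60,28.60
male,16,23.90,28.88
male,16.5,24.19,29.14
male,17,24.46,29.41
male,17.5,24.73,29.70
male,18,25.00,30.00
female,2,18.02,19.81
female,2.5,17.76,19.55
female,3,17.56,19.36
female,3.5,17.40,19.23
female,4,17.28,19.15
female,4.5,17.19,19.12
female,5,17.15,19.17
female,5.5,17.20,19.34
female,6,17.34,19.65
female,6.5,17.53,20.08
female,7,17.75,20.51
female,7.5,18.03,21.01
female,8,18.35,21.57
female,8.5,18.69,22.18
female,9,19.07,22.81
female,9.5,19.45,23.46
female,10,19.86,24.11
female,10.5,20.29,24.77
female,11,20.74,25.42
female,11.5,21.20,26.05
female,12,21.68,26.67
female,12.5,22.14,27.24
female,13,22.58,27.76
female,13.5,22.98,28.20
female,14,23.34,28.57
female,14.5,23.66,28.87
female,15,23.94,29.11
female,15.5,24.17,29.29
female,16,24.37,29.43
female,16.5,24.54,29.56
female,17,24.70,29.69
female,17.5,24.85,29.84
female,18,25.00,30.00
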