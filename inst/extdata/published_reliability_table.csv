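region,variable,unit,icc,ci_low,ci_high,mean,mean_diff,sd_diff,loa_low,loa_high,sem,mdc
whole,force_time_integral,N.s,0.76,0.30,0.92,73.72,-2.08,18.57,-38.47,34.31,13.13,36.39
whole,pressure_time_integral,kPa.s,0.89,0.70,0.96,55.40,0.63,10.04,-19.05,20.31,7.10,19.68
whole,maximum_force,N,0.79,0.42,0.93,161.30,-7.61,25.00,-56.61,41.40,17.68,49.00
whole,peak_pressure,kPa,0.81,0.47,0.93,136.45,6.84,27.48,-47.01,60.70,19.43,53.85
whole,contact_area,cm2,0.83,0.53,0.94,56.80,-3.69,8.15,-19.66,12.27,5.76,15.97
whole,contact_time,ms,0.37,0.00,0.78,669.93,4.29,137.30,-264.81,273.40,97.08,269.11
hindfoot,force_time_integral,N.s,0.83,0.51,0.94,17.44,-1.43,11.35,-23.67,20.82,8.02,22.24
hindfoot,pressure_time_integral,kPa.s,0.97,0.92,0.99,21.41,0.62,12.01,-22.93,24.16,8.49,23.54
hindfoot,maximum_force,N,0.92,0.77,0.97,70.50,-6.38,28.65,-62.53,49.77,20.26,56.15
hindfoot,peak_pressure,kPa,0.88,0.65,0.96,78.56,-3.84,18.48,-40.06,32.37,13.07,36.22
hindfoot,contact_area,cm2,0.91,0.75,0.97,13.68,-1.76,6.19,-13.89,10.36,4.38,12.13
hindfoot,contact_time,ms,0.86,0.62,0.95,365.79,38.16,272.29,-495.53,571.85,192.54,533.69
midfoot,force_time_integral,N.s,0.91,0.75,0.97,15.32,0.52,3.14,-5.63,6.67,2.22,6.15
midfoot,pressure_time_integral,kPa.s,0.97,0.92,0.99,30.19,0.91,5.95,-10.75,12.57,4.21,11.66
midfoot,maximum_force,N,0.91,0.74,0.97,47.92,-2.32,7.84,-17.69,13.05,5.54,15.37
midfoot,peak_pressure,kPa,0.97,0.92,0.99,74.89,1.19,8.31,-15.09,17.47,5.87,16.28
midfoot,contact_area,cm2,0.98,0.94,0.99,16.54,-0.34,2.07,-4.39,3.72,1.46,4.06
midfoot,contact_time,ms,0.73,0.25,0.90,621.32,9.79,118.82,-223.09,242.67,84.02,232.88
forefoot,force_time_integral,N.s,0.73,0.25,0.90,40.95,-1.18,11.14,-23.02,20.66,7.88,21.84
forefoot,pressure_time_integral,kPa.s,0.97,0.92,0.99,42.35,1.53,7.30,-12.77,15.83,5.16,14.30
forefoot,maximum_force,N,0.73,0.26,0.90,123.44,-5.93,23.40,-51.80,39.95,16.55,45.87
forefoot,peak_pressure,kPa,0.44,0.00,0.81,124.59,8.68,28.00,-46.19,63.55,19.80,54.87
forefoot,contact_area,cm2,0.68,0.07,0.89,25.59,-3.57,7.21,-17.70,10.55,5.10,14.12
forefoot,contact_time,ms,0.55,0.00,0.85,578.39,22.66,194.57,-358.70,404.02,137.58,381.36
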