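block,measure,denominator,threshold_pct,line,value,unit
catastrophic,head_count,total_expenditure,5,NA,12.1,percent
catastrophic,head_count,total_expenditure,10,NA,5.5,percent
catastrophic,head_count,total_expenditure,15,NA,3.3,percent
catastrophic,head_count,total_expenditure,25,NA,1.2,percent
catastrophic,head_count,capacity_to_pay,15,NA,7.0,percent
catastrophic,head_count,capacity_to_pay,25,NA,3.4,percent
catastrophic,head_count,capacity_to_pay,40,NA,1.1,percent
catastrophic,ci_incidence,total_expenditure,5,NA,0.03,index
catastrophic,ci_incidence,total_expenditure,10,NA,0.09,index
catastrophic,ci_incidence,total_expenditure,15,NA,0.17,index
catastrophic,ci_incidence,total_expenditure,25,NA,0.32,index
catastrophic,ci_incidence,capacity_to_pay,15,NA,0.00,index
catastrophic,ci_incidence,capacity_to_pay,25,NA,0.08,index
catastrophic,ci_incidence,capacity_to_pay,40,NA,0.29,index
catastrophic,weighted_head_count,total_expenditure,5,NA,11.7,percent
catastrophic,weighted_head_count,total_expenditure,10,NA,5.0,percent
catastrophic,weighted_head_count,total_expenditure,15,NA,2.7,percent
catastrophic,weighted_head_count,total_expenditure,25,NA,0.9,percent
catastrophic,weighted_head_count,capacity_to_pay,15,NA,7.0,percent
catastrophic,weighted_head_count,capacity_to_pay,25,NA,3.1,percent
catastrophic,weighted_head_count,capacity_to_pay,40,NA,0.8,percent
overshoot,mean_overshoot,total_expenditure,5,NA,0.99,percent
overshoot,mean_overshoot,total_expenditure,10,NA,0.58,percent
overshoot,mean_overshoot,total_expenditure,15,NA,0.37,percent
overshoot,mean_overshoot,total_expenditure,25,NA,0.16,percent
overshoot,mean_overshoot,capacity_to_pay,15,NA,0.96,percent
overshoot,mean_overshoot,capacity_to_pay,25,NA,0.47,percent
overshoot,mean_overshoot,capacity_to_pay,40,NA,0.17,percent
overshoot,ci_overshoot,total_expenditure,5,NA,0.17,index
overshoot,ci_overshoot,total_expenditure,10,NA,0.25,index
overshoot,ci_overshoot,total_expenditure,15,NA,0.33,index
overshoot,ci_overshoot,total_expenditure,25,NA,0.46,index
overshoot,ci_overshoot,capacity_to_pay,15,NA,0.14,index
overshoot,ci_overshoot,capacity_to_pay,25,NA,0.24,index
overshoot,ci_overshoot,capacity_to_pay,40,NA,0.39,index
overshoot,mean_positive_overshoot,total_expenditure,5,NA,8.13,percent
overshoot,mean_positive_overshoot,total_expenditure,10,NA,10.61,percent
overshoot,mean_positive_overshoot,total_expenditure,15,NA,11.32,percent
overshoot,mean_positive_overshoot,total_expenditure,25,NA,12.97,percent
overshoot,mean_positive_overshoot,capacity_to_pay,15,NA,13.68,percent
overshoot,mean_positive_overshoot,capacity_to_pay,25,NA,14.07,percent
overshoot,mean_positive_overshoot,capacity_to_pay,40,NA,15.05,percent
poverty,head_count_gross,NA,NA,mongolia_national_2012,22.26,percent
poverty,head_count_net,NA,NA,mongolia_national_2012,23.04,percent
poverty,head_count_absolute,NA,NA,mongolia_national_2012,0.78,percent_points
poverty,head_count_relative,NA,NA,mongolia_national_2012,3.51,percent
poverty,gap_gross,NA,NA,mongolia_national_2012,6953.57,mnt
poverty,gap_net,NA,NA,mongolia_national_2012,7284.22,mnt
poverty,gap_absolute,NA,NA,mongolia_national_2012,330.65,mnt
poverty,gap_relative,NA,NA,mongolia_national_2012,4.76,percent
poverty,normalized_gap_gross,NA,NA,mongolia_national_2012,5.86,percent
poverty,normalized_gap_net,NA,NA,mongolia_national_2012,6.14,percent
poverty,normalized_gap_absolute,NA,NA,mongolia_national_2012,0.28,percent_points
poverty,normalized_gap_relative,NA,NA,mongolia_national_2012,4.76,percent
poverty,nmpg_gross,NA,NA,mongolia_national_2012,26.33,percent
poverty,nmpg_net,NA,NA,mongolia_national_2012,26.64,percent
poverty,nmpg_absolute,NA,NA,mongolia_national_2012,0.32,percent_points
poverty,nmpg_relative,NA,NA,mongolia_national_2012,1.20,percent
poverty,head_count_gross,NA,NA,worldbank_190ppp_2012,0.22,percent
poverty,head_count_net,NA,NA,worldbank_190ppp_2012,0.25,percent
poverty,head_count_absolute,NA,NA,worldbank_190ppp_2012,0.03,percent_points
poverty,head_count_relative,NA,NA,worldbank_190ppp_2012,15.21,percent
poverty,gap_gross,NA,NA,worldbank_190ppp_2012,16.56,mnt
poverty,gap_net,NA,NA,worldbank_190ppp_2012,20.13,mnt
poverty,gap_absolute,NA,NA,worldbank_190ppp_2012,3.57,mnt
poverty,gap_relative,NA,NA,worldbank_190ppp_2012,21.55,percent
poverty,normalized_gap_gross,NA,NA,worldbank_190ppp_2012,0.05,percent
poverty,normalized_gap_net,NA,NA,worldbank_190ppp_2012,0.06,percent
poverty,normalized_gap_absolute,NA,NA,worldbank_190ppp_2012,0.01,percent_points
poverty,normalized_gap_relative,NA,NA,worldbank_190ppp_2012,21.57,percent
poverty,nmpg_gross,NA,NA,worldbank_190ppp_2012,22.07,percent
poverty,nmpg_net,NA,NA,worldbank_190ppp_2012,23.29,percent
poverty,nmpg_absolute,NA,NA,worldbank_190ppp_2012,1.22,percent_points
poverty,nmpg_relative,NA,NA,worldbank_190ppp_2012,5.51,percent
descriptives,mean_oop_all,NA,NA,NA,25086.5,mnt
descriptives,outpatient_use_all,NA,NA,NA,15.6,percent
descriptives,inpatient_use_all,NA,NA,NA,29.6,percent
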