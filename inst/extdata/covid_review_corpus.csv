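review_id,intervention,review_type,is_nma,outcome,polarity,n_rcts_included,n_non_rct,n_no_concern,k_original,measure,est_original,ci_low_original,ci_high_original,k_sensitivity,est_sensitivity,ci_low_sensitivity,ci_high_sensitivity,estimable_sensitivity
Popp-2021a,Antibiotics,cochrane,FALSE,mortality,lower_is_benefit,11,0,6,4,RR,0.98,0.90,1.06,3,0.98,0.90,1.06,TRUE
Zhang-2021-abx,Antibiotics,non_cochrane,TRUE,mortality,lower_is_benefit,16,0,8,12,OR,0.94,0.62,1.52,8,,,,FALSE
Flumignan-2022,Anticoagulants,cochrane,FALSE,mortality,lower_is_benefit,4,0,1,4,RR,1.03,0.92,1.16,1,1.00,0.86,1.15,TRUE
Waheed-2022,Anticoagulants,non_cochrane,FALSE,mortality,lower_is_benefit,12,9,1,9,OR,0.63,0.54,0.72,1,1.08,0.85,1.38,TRUE
Mikolajewska-2021,Colchicine,cochrane,FALSE,mortality,lower_is_benefit,4,0,1,2,RR,1.00,0.93,1.08,1,1.01,0.94,1.08,TRUE
Kow-2022,Colchicine,non_cochrane,FALSE,mortality,lower_is_benefit,10,0,3,9,OR,0.76,0.53,1.07,3,1.01,0.93,1.10,TRUE
Piechotta-2021,Convalescent plasma,cochrane,FALSE,mortality,lower_is_benefit,12,0,5,7,RR,0.98,0.92,1.05,5,0.98,0.92,1.05,TRUE
Deng-2022-cp,Convalescent plasma,non_cochrane,TRUE,mortality,lower_is_benefit,32,0,13,27,OR,0.93,0.84,1.03,11,,,,FALSE
Singh-2021,Hydroxychloroquine or chloroquine,cochrane,FALSE,mortality,lower_is_benefit,14,0,5,9,RR,1.09,0.99,1.19,4,1.09,0.99,1.19,TRUE
Siemieniuk-2020-hcq,Hydroxychloroquine or chloroquine,non_cochrane,TRUE,mortality,lower_is_benefit,45,0,10,35,RR,1.09,0.93,1.27,8,,,,FALSE
Griesel-2022,Inhaled corticosteroids,cochrane,FALSE,mortality,lower_is_benefit,3,0,2,3,RR,0.61,0.22,1.67,2,0.61,0.22,1.67,TRUE
Zhang-2021-ics,Inhaled corticosteroids,non_cochrane,TRUE,mortality,lower_is_benefit,4,0,2,1,OR,0.95,0.63,1.69,1,0.95,0.63,1.69,TRUE
Davidson-2022,Interleukin-1 blocking agents,cochrane,FALSE,clinical_improvement,higher_is_benefit,6,0,2,3,RR,1.08,0.97,1.20,2,1.12,1.03,1.21,TRUE
Naveed-2022,Interleukin-1 blocking agents,non_cochrane,FALSE,mortality,lower_is_benefit,4,1,1,16,RR,1.04,0.76,1.41,1,0.93,0.47,1.83,TRUE
Ghosn-2021,Interleukin-6 blocking agents,cochrane,FALSE,clinical_improvement,higher_is_benefit,10,0,2,7,RR,1.06,1.00,1.13,1,1.14,1.08,1.21,TRUE
Yu-2022,Interleukin-6 blocking agents,non_cochrane,FALSE,mortality,lower_is_benefit,17,0,4,16,RR,0.88,0.82,0.95,4,0.84,0.78,0.91,TRUE
Popp-2021b,Ivermectin,cochrane,FALSE,mortality,lower_is_benefit,14,0,3,2,RR,0.60,0.14,2.51,0,,,,FALSE
Izcovich-2022,Ivermectin,non_cochrane,FALSE,mortality,lower_is_benefit,29,0,4,12,RR,0.50,0.28,0.88,1,0.33,0.01,8.05,TRUE
Ansems-2021,Remdesivir,cochrane,FALSE,mortality,lower_is_benefit,5,0,3,4,RR,0.93,0.81,1.06,3,0.90,0.75,1.08,TRUE
Lee-2022,Remdesivir,non_cochrane,FALSE,mortality,lower_is_benefit,8,0,4,8,RR,0.92,0.78,1.08,4,0.91,0.71,1.15,TRUE
Kreuzberger-2021,SARS-CoV-2-neutralizing monoclonal antibodies,cochrane,FALSE,mortality,lower_is_benefit,6,0,2,1,RR,0.94,0.87,1.02,1,0.94,0.87,1.02,TRUE
Deng-2022-mab,SARS-CoV-2-neutralizing monoclonal antibodies,non_cochrane,TRUE,mortality,lower_is_benefit,18,0,4,5,OR,0.86,0.73,1.02,2,,,,FALSE
Wagner-2021,Systemic corticosteroids,cochrane,FALSE,mortality,lower_is_benefit,11,0,4,9,RR,0.89,0.80,1.00,4,0.90,0.84,0.97,TRUE
Siemieniuk-2020-sc,Systemic corticosteroids,non_cochrane,TRUE,mortality,lower_is_benefit,14,0,4,11,RR,0.83,0.69,0.98,4,,,,FALSE
Stroehlein-2021,Vitamin D,cochrane,FALSE,mortality,lower_is_benefit,3,0,0,2,RR,0.58,0.05,7.20,0,,,,FALSE
Hosseini-2022,Vitamin D,non_cochrane,FALSE,mortality,lower_is_benefit,9,1,0,4,RR,0.56,0.25,1.25,0,,,,FALSE
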