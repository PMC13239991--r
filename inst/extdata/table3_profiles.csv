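label,n_products,pct_fortified,energy,protein,fat,sfa,pufa,carbohydrate,total_sugar,added_sugar,vitamin_b2,vitamin_b12,calcium,iron,iodine,ghge_100g,lu_100g
dairy,1308,NA,92.96,4.60,5.01,3.18,0.14,6.04,5.77,1.51,0.18,0.46,0.14,0.12,10.6,0.28,0.27
pbda_total,107,51,52.93,2.45,1.65,0.25,0.81,6.70,2.90,0.37,0.03,0.00,0.08,0.64,1.0,0.05,0.10
pbda_fortified,55,100,50.12,2.96,1.52,0.23,0.86,6.72,4.00,2.54,0.05,0.29,0.12,0.73,0.81,NA,NA
pbda_nonfortified,52,0,54.26,1.78,1.96,0.27,0.81,6.70,1.41,0.00,0.02,0.00,0.01,0.53,0.74,NA,NA
pbda_soy,51,67,56.97,3.62,1.92,0.26,1.11,3.98,3.95,3.11,0.05,0.12,0.12,0.86,0.52,NA,NA
pbda_oat,23,48,52.93,1.71,1.29,0.21,0.58,8.14,3.67,0.00,0.01,0.00,0.01,0.51,2.52,NA,NA
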