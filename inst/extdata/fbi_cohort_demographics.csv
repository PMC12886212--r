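cohort_id,cohort_order,n,age_mean,wpi_mean,ssi_mean,acr_met_n,sfn_mean,pcs_mean
C1,1,3,56.33,9.33,9.67,2,64.00,30.67
C2,2,3,54.33,10.67,8.67,2,56.67,30.00
C3,3,3,47.67,13.67,6.33,2,56.33,22.00
C4,4,3,51.67,10.00,7.00,3,62.00,26.33
C5,5,2,50.00,12.50,8.50,1,61.50,28.00
C6,6,3,50.00,16.33,9.33,3,73.67,27.00
C7,7,3,56.67,7.67,7.67,3,59.67,21.33
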