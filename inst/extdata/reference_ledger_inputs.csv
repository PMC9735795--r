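peptide,dh_itc,n_h,neg_log_kd,n_his,dh_std_printed,dh_cysh_printed,dh_zn_pep_printed
CP-1991,-20.87,1.56,14.49,2,-13.06,13.23,-26.29
CP-2015,-18.83,1.64,12.30,2,-10.58,13.97,-24.44
CP-1991-K/S,-16.82,1.68,14.04,2,-8.37,14.31,-22.68
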