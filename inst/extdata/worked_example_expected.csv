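organoid_id,t_s,t_c,t_g1,t_g2m,flags,error
ORG_OK,6,24,12,6,,NA
ORG_ZERO_L,NA,NA,NA,NA,,"estimate_ts: l_cells is 0: no cells left S phase during the IdU-only window, so t_s is unidentifiable (infinite estimate)"
ORG_ZERO_G2M,1.5,6,4.5,0,,NA
ORG_ALL_G1,NA,NA,NA,NA,,estimate_tc: n_s_flow is 0: cannot scale t_s to the full cycle
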