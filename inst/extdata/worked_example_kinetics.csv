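organoid_id,line_id,genotype,batch_id,l_cells,s_cells,t_i,n_total_singlets,n_sox2,n_pcells,n_g1,n_s_flow,n_g2m,n_tuj1_ki67,expect_error
ORG_OK,FACS51,control,RF1,50,200,1.5,20000,15000,12000,6000,3000,3000,1500,FALSE
ORG_ZERO_L,DELD5,deletion,RF1,0,150,1.5,8000,6000,4000,2000,1500,500,600,TRUE
ORG_ZERO_G2M,FACS52,control,RF2,100,100,1.5,5000,4000,2000,1500,500,0,250,FALSE
ORG_ALL_G1,DELA3,deletion,RF2,40,80,1.5,4000,3000,1000,1000,0,0,120,TRUE
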