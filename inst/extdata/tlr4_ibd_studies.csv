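study_id,year,country,ethnicity,disease,snp,control_group_id,n_case,n_ctrl,genotyping_method
Mohammadi,2013,Iran,Asians,UC,rs4986790;rs4986791,Mohammadi,85,256,PCR-RFLP
Meena,2013,India,Asians,UC,rs4986790;rs4986791,Meena,199,201,PCR-RFLP
Meena,2013,India,Asians,CD,rs4986790;rs4986791,Meena,46,201,PCR-RFLP
Sivaram,2012,India,Asians,UC,rs4986790,Sivaram,139,176,AS-PCR
Magalhaes Queiroz,2009,Brazil,Caucasians,UC,rs4986790,Magalhaes Queiroz,42,541,PCR-RFLP
Magalhaes Queiroz,2009,Brazil,Caucasians,CD,rs4986790,Magalhaes Queiroz,43,541,PCR-RFLP
Rigoli,2008,Italy,Caucasians,UC,rs4986790;rs4986791,Rigoli,45,103,PCR-RFLP
Rigoli,2008,Italy,Caucasians,CD,rs4986790;rs4986791,Rigoli,133,103,PCR-RFLP
Lappalainen,2008,Finland,Caucasians,UC,rs4986790;rs4986791,Lappalainen,459,190,PCR-RFLP
Lappalainen,2008,Finland,Caucasians,CD,rs4986790;rs4986791,Lappalainen,240,190,PCR-RFLP
Hong,2007,New Zealand,Caucasians,CD,rs4986790;rs4986791,Hong,182,188,PCR-RFLP
Browning,2007,New Zealand,Caucasians,UC,rs4986790;rs4986791,Browning,405,416,TaqMan assay
Browning,2007,New Zealand,Caucasians,CD,rs4986790;rs4986791,Browning,389,416,TaqMan assay
Baumgart,2007,Germany,Caucasians,UC,rs4986790,Baumgart,145,403,PCR-RFLP
Baumgart,2007,Germany,Caucasians,CD,rs4986790,Baumgart,235,403,PCR-RFLP
Oostenbrug,2005,Netherlands,Caucasians,UC,rs4986790;rs4986791,Oostenbrug,217,299,PCR-RFLP
Oostenbrug,2005,Netherlands,Caucasians,CD,rs4986790;rs4986791,Oostenbrug,504,299,PCR-RFLP
Brand,2005,Germany,Caucasians,CD,rs4986790;rs4986791,Brand,204,199,AS-PCR
Torok,2004,Germany,Caucasians,UC,rs4986790;rs4986791,Torok,98,145,PCR-RFLP
Torok,2004,Germany,Caucasians,CD,rs4986790;rs4986791,Torok,102,145,PCR-RFLP
Franchimont,2004,Belgium,Caucasians,UC,rs4986790,Franchimont,163,139,PCR-RFLP
Franchimont,2004,Belgium,Caucasians,CD,rs4986790,Franchimont,334,139,PCR-RFLP
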