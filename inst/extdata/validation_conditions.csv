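# thsurr-conditions/1
label,s_IFNg,s_IL12,s_IL6,s_TGFb,c_IFNg,c_IL12,c_IL6,c_TGFb,readout,direction,note
study1_il17,0,0,1,1,0,0,0,0,IL17,up,"IL-6 (100) + TGFb (10) versus unstimulated control; IL-17 secretion rises strongly"
study1_rorgt,0,0,1,1,0,0,0,0,RORgt,up,"Same stimulation; RORgt induction accompanies Th17 commitment"
study2_foxp3_up,0,0,1,1,0,0,0,1,FOXP3,up,"IL-6 added to TGFb-induced cultures versus TGFb alone; this study reports FOXP3 up"
study3_foxp3_down,0,0,0.2,0.3,0,0,0,0.3,FOXP3,down,"IL-6 (20) added to TGFb (3) versus TGFb alone; FOXP3+ Treg induction abolished"
study4_tbet,0,1,0,0,0,0,0,0,Tbet,up,"IL-12 stimulation versus unstimulated control; T-bet induction (Th1)"
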