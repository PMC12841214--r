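scale,feature,direction,threshold_low,threshold_high,reference
MB,mb,lower_is_riskier,24.0,11.0,Franchignoni et al. 2010 (Mini-BESTest)
FIM (total),fim_total,lower_is_riskier,72.0,37.0,FIM total score bands
FIM (motor domain),fim_motor,lower_is_riskier,65.0,26.0,FIM motor-domain bands
POMA-B,poma_b,lower_is_riskier,14.0,7.0,Tinetti POMA balance bands
TUG Test (TTD),tug_ttd,higher_is_riskier,12.0,22.0,TUG community cut-offs
FES-I,fes_i,higher_is_riskier,19.0,28.0,FES-I concern bands
Conley Scale,conley,higher_is_riskier,2.0,7.0,Conley fall-risk bands
10 MWT,mwt10_speed,lower_is_riskier,1.0,0.6,10-metre walk speed bands
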