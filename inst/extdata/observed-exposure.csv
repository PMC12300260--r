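population,dose_mg_per_kg,interval_h,parameter,observed,obs_sd,obs_low,obs_high,source
adult,5,NA,cmax,4.74,NA,NA,NA,Clements 1984
adult,5,NA,auc_inf,18.4,1.65,NA,NA,Clements 1984
adult,20,NA,cmax,17.8,NA,NA,NA,Clements 1984
adult,20,NA,auc_inf,82.5,10.0,NA,NA,Clements 1984
child,12.5,6,cmax,24.3,NA,3.8,35.1,Zuppa 2011
child,12.5,6,auc_tau,37.8,NA,11.3,52.3,Zuppa 2011
infant,12.5,4,cmax,21.9,NA,4.2,25.3,Zuppa 2011
infant,12.5,4,auc_tau,43.3,NA,9.2,79.2,Zuppa 2011
neonate,12.5,4,cmax,19.9,NA,19.3,20.5,Zuppa 2011
neonate,12.5,4,auc_tau,65.6,NA,55.8,75.4,Zuppa 2011
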