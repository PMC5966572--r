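feature,posture,group,mean,sd
ln_mav,P1,PD1,0.0,1.3
ln_mav,P1,PD2,0.8,1.2
ln_mav,P1,ET1,0.5,1.3
ln_mav,P1,ET2,0.7,1.7
ln_mav,P1,PD,0.4,1.3
ln_mav,P1,ET,0.6,1.5
ln_mav,P2,PD1,0.4,1.5
ln_mav,P2,PD2,-0.4,2.0
ln_mav,P2,ET1,-2.0,0.7
ln_mav,P2,ET2,-2.1,0.5
ln_mav,P2,PD,-0.3,1.8
ln_mav,P2,ET,-2.1,0.6
domfreq_psd,P1,PD1,6.2,1.7
domfreq_psd,P1,PD2,5.9,1.8
domfreq_psd,P1,ET1,6.9,1.7
domfreq_psd,P1,ET2,7.0,1.9
domfreq_psd,P1,PD,6.0,1.7
domfreq_psd,P1,ET,7.1,1.8
domfreq_psd,P2,PD1,5.0,1.2
domfreq_psd,P2,PD2,5.5,1.9
domfreq_psd,P2,ET1,7.7,1.9
domfreq_psd,P2,ET2,8.6,1.9
domfreq_psd,P2,PD,5.2,1.6
domfreq_psd,P2,ET,8.1,2.0
domfreq_bispec,P1,PD1,5.2,1.9
domfreq_bispec,P1,PD2,5.2,1.3
domfreq_bispec,P1,ET1,6.3,1.9
domfreq_bispec,P1,ET2,6.3,1.8
domfreq_bispec,P1,PD,5.2,1.3
domfreq_bispec,P1,ET,6.4,1.8
domfreq_bispec,P2,PD1,4.6,0.9
domfreq_bispec,P2,PD2,4.7,1.2
domfreq_bispec,P2,ET1,6.0,1.3
domfreq_bispec,P2,ET2,6.7,1.5
domfreq_bispec,P2,PD,4.7,1.0
domfreq_bispec,P2,ET,6.7,1.4
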