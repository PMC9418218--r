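i,alpha_re,alpha_im,K_re,K_im
1,12.83767675,1.666063445,-36902.08210,196990.4257
2,12.22613209,5.012718792,61277.02524,-95408.62551
3,10.93430308,8.409673116,-28916.56288,18169.18531
4,8.776434715,11.92185389,4655.361138,-1.901528642
5,5.225453361,15.72952905,-118.7414011,-141.3036911
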