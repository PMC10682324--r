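scenario,pricing_kind,quantity,country,point,ci_lo,ci_hi
concurrent,pay_per_use,cost_eur,USA,4.2,2.6,5.8
concurrent,pay_per_use,cost_eur,UK,2.7,1.7,3.8
concurrent,pay_per_use,cost_eur,Poland,1.0,0.6,1.3
concurrent,one_off_license,workload_thousand,USA,12.3,8.9,20.2
concurrent,one_off_license,workload_thousand,UK,19.0,13.7,31.1
concurrent,one_off_license,workload_thousand,Poland,53.6,38.6,87.9
concurrent,yearly_subscription,workload_thousand,USA,4.8,3.4,7.8
concurrent,yearly_subscription,workload_thousand,UK,7.4,5.3,12.1
concurrent,yearly_subscription,workload_thousand,Poland,20.8,15.0,34.0
prescreen_best,pay_per_use,cost_eur,USA,5.4,3.8,7.1
prescreen_best,pay_per_use,cost_eur,UK,3.5,2.4,4.6
prescreen_best,pay_per_use,cost_eur,Poland,1.3,0.9,1.6
prescreen_best,one_off_license,workload_thousand,USA,9.4,7.2,13.7
prescreen_best,one_off_license,workload_thousand,UK,14.5,11.1,21.1
prescreen_best,one_off_license,workload_thousand,Poland,40.8,31.2,59.6
prescreen_best,yearly_subscription,workload_thousand,USA,3.6,2.8,5.3
prescreen_best,yearly_subscription,workload_thousand,UK,5.6,4.3,8.2
prescreen_best,yearly_subscription,workload_thousand,Poland,15.8,12.1,23.1
prescreen_worst,pay_per_use,cost_eur,USA,3.5,2.3,4.5
prescreen_worst,pay_per_use,cost_eur,UK,2.3,1.5,2.9
prescreen_worst,pay_per_use,cost_eur,Poland,0.8,0.5,1.0
prescreen_worst,one_off_license,workload_thousand,USA,14.9,11.4,21.8
prescreen_worst,one_off_license,workload_thousand,UK,23.0,17.6,33.6
prescreen_worst,one_off_license,workload_thousand,Poland,65.0,49.7,94.9
prescreen_worst,yearly_subscription,workload_thousand,USA,5.8,4.4,8.4
prescreen_worst,yearly_subscription,workload_thousand,UK,8.9,6.8,13.0
prescreen_worst,yearly_subscription,workload_thousand,Poland,25.2,19.3,36.8
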