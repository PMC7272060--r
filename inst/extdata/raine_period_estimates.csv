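period_id,method,n_surveys,mean_total,n_hat,se
Dec 2013,SO,6,3167.2,58817.8,6095.1
Dec 2013,UWV,1,4289.0,102142.9,10969.9
Dec 2014,SO,3,1002.7,14439.1,1174.1
Dec 2014,UWV,3,534.0,18827.3,2470.9
Feb 2016,SO,5,169.2,4708.7,1116.3
Feb 2016,UWV,6,194.8,5398.2,1351.5
Nov 2016,SO,6,728.8,8838.1,1074.4
Nov 2016,UWV,6,1000.5,13180.8,1756.6
Dec 2016,SO,6,705.5,12377.5,1089.1
Dec 2016,UWV,5,1275.8,18135.9,1496.1
Dec 2016,UAV,3,1460.0,19682.9,1553.2
Dec 2017,SO,2,1596.5,20009.4,1618.7
Dec 2017,UWV,3,1679.3,33263.1,3198.1
Dec 2017,UAV,3,4622.3,37035.0,2334.0
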