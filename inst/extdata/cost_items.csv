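resource_label,n_units,unit_cost,currency,source,period
IMT device,1,1200,USD,market price,1 unit
Treadmill,1,1150,USD,market price,1 unit
Resistance exercise station,1,1132,USD,market price,2 units
Oxygen supplier device,1,960,USD,market price,2 units
Rehabilitation team salaries,1,2347,USD,Health Secretary,per month
"Supplies (cleaners, nose catheter, PPE)",1,1345,USD,SIGTAP,200 units
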