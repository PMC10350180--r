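"neuron_id","class","x","y","z","layer"
"N001","K1",-6.7668857096819,67.2320100477981,-37.0786217750393,"L3"
"N002","K1",-44.0668003584303,58.8832345684234,-8.63051212054546,"L2"
"N003","K1",-13.6231319857416,-87.0665369495634,-240.884134061439,"L1"
"N004","K1",-47.4539466240999,-60.7835037041657,23.3639890928554,"L1"
"N005","K1",33.7118875663269,-103.559126480071,5.54280710907592,"L1"
"N006","K1",-65.0430781817637,120.868245788628,-21.7287103967918,"L3"
"N007","K2",624.660314289709,-18.9879896083633,102.649830580235,"L2"
"N008","K2",499.240829134245,-32.0066225327388,1.75884990569673,"L2"
"N009","K2",639.421390495823,-88.5739327444824,-84.839158599185,"L1"
"N010","K2",656.09290554861,48.2165394085683,-161.64875846683,"L2"
"N011","K2",620.534043430043,77.0968871335665,-124.311312976874,"L3"
"N012","K2",438.108609702103,100.86223644206,34.2764623104846,"L3"
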