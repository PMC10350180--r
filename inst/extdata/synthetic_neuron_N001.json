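{"neuron":{"idString":"N001","soma":{"x":-6.7668857096819,"y":67.2320100477981,"z":-37.0786217750393,"allenId":"SRC","layer":"L3"},"axon":[{"sampleNumber":1,"x":-1066.98908982002,"y":-904.018377551314,"z":2561.67137822496,"parentNumber":-1,"allenId":"R01"},{"sampleNumber":2,"x":223.224440998851,"y":2687.86455337371,"z":2069.17137822496,"parentNumber":-1,"allenId":"R02"},{"sampleNumber":3,"x":2119.65607282304,"y":-2706.31019062717,"z":1376.67137822496,"parentNumber":-1,"allenId":"R03"},{"sampleNumber":4,"x":-4110.12540251382,"y":793.058354686075,"z":487.921378224961,"parentNumber":-1,"allenId":"R04"},{"sampleNumber":5,"x":3818.9515078004,"y":2500.84089626157,"z":-608.328621775039,"parentNumber":-1,"allenId":"R05"},{"sampleNumber":6,"x":-1207.65844767685,"y":-4400.02474257971,"z":-1908.32862177504,"parentNumber":-1,"allenId":"R06"},{"sampleNumber":7,"x":-1938.8683493626,"y":3787.37580722154,"z":-3393.32862177504,"parentNumber":-1,"allenId":"R07"},{"sampleNumber":8,"x":2630.76552390623,"y":-895.99059570108,"z":-5112.07862177504,"parentNumber":-1,"allenId":"R08"},{"sampleNumber":9,"x":-1070.55886155103,"y":-907.288580876563,"z":2570.42137822496,"parentNumber":1,"allenId":"R01"},{"sampleNumber":10,"x":223.906907843683,"y":2695.64091106904,"z":2075.42137822496,"parentNumber":2,"allenId":"R02"},{"sampleNumber":11,"x":2125.29645202339,"y":-2713.66706649103,"z":1380.42137822496,"parentNumber":3,"allenId":"R03"},{"sampleNumber":12,"x":3827.32288284091,"y":2506.16607982002,"z":-609.578621775039,"parentNumber":5,"allenId":"R05"},{"sampleNumber":13,"x":-1210.06504399342,"y":-4408.97716092165,"z":-1912.07862177504,"parentNumber":6,"allenId":"R06"},{"sampleNumber":14,"x":-1942.46630367108,"y":3794.30344930194,"z":-3399.57862177504,"parentNumber":7,"allenId":"R07"},{"sampleNumber":15,"x":-1074.12863328204,"y":-910.558784201813,"z":2579.17137822496,"parentNumber":9,"allenId":"R01"},{"sampleNumber":16,"x":224.589374688515,"y":2703.41726876437,"z":2081.67137822496,"parentNumber":10,"allenId":"R02"},{"sampleNumber":17,"x":2130.93683122374,"y":-2721.02394235489,"z":1384.17137822496,"parentNumber":11,"allenId":"R03"},{"sampleNumber":18,"x":3835.69425788141,"y":2511.49126337847,"z":-610.828621775039,"parentNumber":12,"allenId":"R05"},{"sampleNumber":19,"x":-1212.47164030998,"y":-4417.92957926359,"z":-1915.82862177504,"parentNumber":13,"allenId":"R06"},{"sampleNumber":20,"x":-1946.06425797955,"y":3801.23109138234,"z":-3405.82862177504,"parentNumber":14,"allenId":"R07"},{"sampleNumber":21,"x":-1077.69840501305,"y":-913.828987527062,"z":2587.92137822496,"parentNumber":15,"allenId":"R01"},{"sampleNumber":22,"x":225.271841533348,"y":2711.1936264597,"z":2087.92137822496,"parentNumber":16,"allenId":"R02"},{"sampleNumber":23,"x":2136.57721042409,"y":-2728.38081821875,"z":1387.92137822496,"parentNumber":17,"allenId":"R03"},{"sampleNumber":24,"x":3844.06563292191,"y":2516.81644693693,"z":-612.078621775039,"parentNumber":18,"allenId":"R05"},{"sampleNumber":25,"x":-1949.66221228803,"y":3808.15873346273,"z":-3412.07862177504,"parentNumber":20,"allenId":"R07"},{"sampleNumber":26,"x":-1081.26817674406,"y":-917.099190852312,"z":2596.67137822496,"parentNumber":21,"allenId":"R01"},{"sampleNumber":27,"x":225.95430837818,"y":2718.96998415503,"z":2094.17137822496,"parentNumber":22,"allenId":"R02"},{"sampleNumber":28,"x":2142.21758962445,"y":-2735.73769408261,"z":1391.67137822496,"parentNumber":23,"allenId":"R03"},{"sampleNumber":29,"x":3852.43700796242,"y":2522.14163049538,"z":-613.328621775039,"parentNumber":24,"allenId":"R05"},{"sampleNumber":30,"x":-1953.26016659651,"y":3815.08637554313,"z":-3418.32862177504,"parentNumber":25,"allenId":"R07"},{"sampleNumber":31,"x":-1084.83794847507,"y":-920.369394177561,"z":2605.42137822496,"parentNumber":26,"allenId":"R01"},{"sampleNumber":32,"x":226.636775223013,"y":2726.74634185036,"z":2100.42137822496,"parentNumber":27,"allenId":"R02"},{"sampleNumber":33,"x":2147.8579688248,"y":-2743.09456994647,"z":1395.42137822496,"parentNumber":28,"allenId":"R03"},{"sampleNumber":34,"x":3860.80838300292,"y":2527.46681405384,"z":-614.578621775039,"parentNumber":29,"allenId":"R05"},{"sampleNumber":35,"x":-1956.85812090499,"y":3822.01401762353,"z":-3424.57862177504,"parentNumber":30,"allenId":"R07"},{"sampleNumber":36,"x":-1088.40772020608,"y":-923.639597502811,"z":2614.17137822496,"parentNumber":31,"allenId":"R01"},{"sampleNumber":37,"x":227.319242067845,"y":2734.52269954569,"z":2106.67137822496,"parentNumber":32,"allenId":"R02"},{"sampleNumber":38,"x":2153.49834802515,"y":-2750.45144581033,"z":1399.17137822496,"parentNumber":33,"allenId":"R03"},{"sampleNumber":39,"x":3869.17975804342,"y":2532.79199761229,"z":-615.828621775039,"parentNumber":34,"allenId":"R05"},{"sampleNumber":40,"x":-1960.45607521347,"y":3828.94165970393,"z":-3430.82862177504,"parentNumber":35,"allenId":"R07"}],"dendrite":null}}
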