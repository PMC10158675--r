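{"heart_rate":{"direction":"higher","cuts":[100,120,140,160]},"dopamine":{"direction":"higher","cuts":[0,5,10,15]},"lactate":{"direction":"higher","cuts":[2,3.5,5,8]},"creatinine":{"direction":"higher","cuts":[100,200,350,500]},"bilirubin":{"direction":"higher","cuts":[20,60,120,240]},"oxygenation_index":{"direction":"lower","cuts":[300,225,150,75]},"gcs":{"direction":"lower","cuts":[14,12,9,6]},"platelets":{"direction":"lower","cuts":[120,80,50,20]}}
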