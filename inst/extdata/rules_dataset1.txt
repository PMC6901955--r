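IF CSGAGFEGTGLRCSLLCLDR<=0.795 THEN type = "Esophageal cancer"
IF CSGFQPMRYPFQDPYHGYGW<=1.056 AND CSGADFVTYATRRVQFMMHK<=1.611 THEN type = "Pancreatic cancer"
IF CSGFLMEHQNLLERSEDAKA<=0.569 AND CSGGEGIQATYHKVGGNFLG>=1.238 THEN type = "Healthy control"
IF CSGTYEPHLVYLATFTDGIP<=0.870 THEN type = "Healthy control"
IF CSGEKIGMEQHYNQWIELMR>=1.036 THEN type = "Multiple myeloma"
IF CSGADFVTYATRRVQFMMHK>=1.282 THEN type = "Brain cancer"
IF Others THEN type = "Breast cancer"
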