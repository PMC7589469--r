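organism,genes,alleles,intervention_types,lifespan_days,lifespan_metric,temperature_c,diet,study_id
C. elegans,,,,20,mean,20,standard,SYNFIG1
C. elegans,g1,,loss-of-function mutation,30,mean,20,standard,SYNFIG1
C. elegans,g2,,loss-of-function mutation,24,mean,20,standard,SYNFIG1
C. elegans,g3,,loss-of-function mutation,23,mean,20,standard,SYNFIG1
C. elegans,g1;g2,,loss-of-function mutation;loss-of-function mutation,44,mean,20,standard,SYNFIG1
C. elegans,g1;g3,,loss-of-function mutation;loss-of-function mutation,42,mean,20,standard,SYNFIG1
C. elegans,g2;g3,,loss-of-function mutation;loss-of-function mutation,28,mean,20,standard,SYNFIG1
C. elegans,g1;g2;g3,,loss-of-function mutation;loss-of-function mutation;loss-of-function mutation,38,mean,20,standard,SYNFIG1
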