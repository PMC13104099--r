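assessor_tier,domain,mean_hms
beginner,1,00:01:22
beginner,2,00:02:32
beginner,3,00:04:19
beginner,4,00:03:27
beginner,5,00:06:03
beginner,6,00:09:15
expert,1,00:01:05
expert,2,00:02:03
expert,3,00:03:49
expert,4,00:03:20
expert,5,00:03:36
expert,6,00:06:59
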