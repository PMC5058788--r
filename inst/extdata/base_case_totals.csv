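analysis,name,total_cost_usd,total_qaly,status
1,KRAS-Cetux,159993.30,1.81,published
1,KRAS-Bev,141396.19,1.75,published
1,RAS-Cetux,157748.27,1.91,published
1,RAS-Bev,140920.25,1.87,published
2,FOLFOX-Cetux,158250.86,1.94,published
2,FOLFOX-Bev,140690.31,1.74,published
2,FOLFIRI-Cetux,152319.29,1.89,published
2,FOLFIRI-Bev,138933.51,2.08,published
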