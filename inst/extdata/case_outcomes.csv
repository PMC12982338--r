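case_id,outcome,situation,peak_lin_acc_g,peak_ang_acc_rads2,end_time_ms
1,1,rear_end_collision,22.1,1039.0,120
2,2,american_football,106.1,12950.0,70
3,1,american_football,84.2,6190.0,70
4,2,american_football,96.0,7428.0,100
5,2,side_impact,27.4,3024.1,140
6,2,american_football,98.8,9117.9,50
7,2,american_football,82.7,6407.4,50
8,0,american_football,62.1,3434.9,50
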