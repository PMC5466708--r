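species,level,analysis,value
human,proteins,current,10456
human,proteins,current_3X,6683
human,proteins,Rcapture_HTP_vs_LTP,12844
human,proteins,Rcapture_noise_adjusted,10239
human,proteins,CF_noise,9160
human,proteins,CF_3X,7582
human,proteins,CF_best_start,8803
human,proteins,CF_best_end,8775
human,proteins,CF_half_exp,7885
mouse,proteins,current,6512
mouse,proteins,current_3X,3827
mouse,proteins,Rcapture_HTP_vs_LTP,11190
mouse,proteins,Rcapture_noise_adjusted,8346
mouse,proteins,CF_noise,7213
mouse,proteins,CF_3X,6789
mouse,proteins,CF_best_start,7167
mouse,proteins,CF_best_end,7099
mouse,proteins,CF_half_exp,6329
arabidopsis,proteins,current,4930
arabidopsis,proteins,current_3X,1815
arabidopsis,proteins,Rcapture_HTP_vs_LTP,NA
arabidopsis,proteins,Rcapture_noise_adjusted,6531
arabidopsis,proteins,CF_noise,4292
arabidopsis,proteins,CF_3X,NA
arabidopsis,proteins,CF_best_start,4558
arabidopsis,proteins,CF_best_end,4292
arabidopsis,proteins,CF_half_exp,2373
yeast,proteins,current,2587
yeast,proteins,current_3X,1630
yeast,proteins,Rcapture_HTP_vs_LTP,2951
yeast,proteins,Rcapture_noise_adjusted,2772
yeast,proteins,CF_noise,2373
yeast,proteins,CF_3X,2297
yeast,proteins,CF_best_start,2328
yeast,proteins,CF_best_end,2304
yeast,proteins,CF_half_exp,2257
human,p_sites,current,86181
human,p_sites,current_3X,27110
human,p_sites,Rcapture_HTP_vs_LTP,229616
human,p_sites,Rcapture_noise_adjusted,124985
human,p_sites,CF_noise,94670
human,p_sites,CF_3X,91500
human,p_sites,CF_best_start,82092
human,p_sites,CF_best_end,86723
human,p_sites,CF_half_exp,89639
mouse,p_sites,current,36438
mouse,p_sites,current_3X,10384
mouse,p_sites,Rcapture_HTP_vs_LTP,155668
mouse,p_sites,Rcapture_noise_adjusted,71456
mouse,p_sites,CF_noise,54031
mouse,p_sites,CF_3X,NA
mouse,p_sites,CF_best_start,45797
mouse,p_sites,CF_best_end,49122
mouse,p_sites,CF_half_exp,36615
arabidopsis,p_sites,current,14796
arabidopsis,p_sites,current_3X,3078
arabidopsis,p_sites,Rcapture_HTP_vs_LTP,NA
arabidopsis,p_sites,Rcapture_noise_adjusted,27815
arabidopsis,p_sites,CF_noise,23531
arabidopsis,p_sites,CF_3X,34457
arabidopsis,p_sites,CF_best_start,15122
arabidopsis,p_sites,CF_best_end,23531
arabidopsis,p_sites,CF_half_exp,6016
yeast,p_sites,current,13244
yeast,p_sites,current_3X,4156
yeast,p_sites,Rcapture_HTP_vs_LTP,40350
yeast,p_sites,Rcapture_noise_adjusted,21343
yeast,p_sites,CF_noise,14533
yeast,p_sites,CF_3X,NA
yeast,p_sites,CF_best_start,12962
yeast,p_sites,CF_best_end,14496
yeast,p_sites,CF_half_exp,11980
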