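# Irregular-step / beyond-control-variability counts transcribed from the
# published figure captions, with the printed two-proportion z statistic,
# the number of printed decimals, and the variance variant under which the
# printed value reproduces. Comparisons whose printed z reproduces under
# neither variant are omitted.
comparison,x1,n1,x2,n2,variant,z_printed,digits
overground_hl_acrylic_pd1_vs_d1d5,3,238,12,218,unpooled,2.49,2
overground_hl_acrylic_pd1_vs_d1d8,3,238,11,218,unpooled,2.29,2
overground_hl_acrylic_pd2_vs_d2d5,4,82,38,82,unpooled,6.91,2
overground_hl_acrylic_pd2_vs_d2d8,4,82,25,88,unpooled,4.39,2
overground_hl_sylgard_pd1_vs_d1d5,2,189,37,177,pooled,6.15,2
overground_hl_sylgard_pd1_vs_d1d8,2,189,51,171,pooled,7.69,2
overground_hl_sylgard_pd2_vs_d2d8,13,81,38,80,pooled,4.29,2
overground_hl_sylgard_pd2_vs_d2d13,13,81,48,83,pooled,5.53,2
overground_fl_acrylic_pd1_vs_d1d5,5,238,7,218,unpooled,0.73,2
overground_fl_acrylic_pd2_vs_d2d5,6,82,14,82,unpooled,1.93,2
overground_fl_acrylic_pd2_vs_d2d8,6,82,17,88,unpooled,2.35,2
overground_fl_sylgard_pd1_vs_d1d5,8,189,23,177,pooled,3.01,2
overground_fl_sylgard_pd1_vs_d1d8,8,189,33,171,unpooled,4.49,2
overground_fl_sylgard_pd2_vs_d2d5,3,81,34,76,unpooled,6.75,2
overground_fl_sylgard_pd2_vs_d2d8,3,81,24,80,unpooled,4.75,2
swim_hl_lapn_pd1_vs_d1d5,4,294,8,302,unpooled,1.13,2
swim_hl_lapn_pd1_vs_d1d8,4,294,8,278,unpooled,1.25,2
swim_hl_ldpn_pd1_vs_d1d5,9,408,23,416,unpooled,2.5,1
swim_hl_ldpn_pd1_vs_d1d8,9,408,24,468,unpooled,2.33,2
bbb_raw_scores_control_vs_dox,0,48,28,80,pooled,4.64,2
postsci_hl_pd2_vs_d2d5,33,114,8,107,pooled,4.10,2
postsci_hl_pd2_vs_d2d8,33,114,17,108,pooled,2.35,2
postsci_hl_pd3_vs_d3d13,18,107,12,107,pooled,1.18,2
postsci_het_pd2_vs_d2d5,47,114,42,107,pooled,0.30,2
postsci_het_pd2_vs_d2d8,47,114,28,108,pooled,2.41,2
postsci_het_pd3_vs_d3d13,44,107,36,107,pooled,1.13,2
postsci_het_collapsed_control_vs_dox,143,332,192,530,pooled,2.01,2
postsci_fl_pd2_vs_d2d5,12,114,9,107,pooled,0.54,2
postsci_fl_pd2_vs_d2d8,12,114,7,108,pooled,1.08,2
postsci_fl_pd3_vs_d3d5,8,107,11,108,pooled,0.70,2
postsci_fl_pd3_vs_d3d8,8,107,5,100,pooled,0.73,2
postsci_fl_pd3_vs_d3d13,8,107,3,107,pooled,1.55,2
postsci_fl_collapsed_control_vs_dox,30,332,35,530,pooled,1.32,2
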