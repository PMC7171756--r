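country,arm,category,item,cost_first,cost_subsequent
Germany,cabozantinib,drug,cabozantinib,6841,6841
Germany,cabozantinib,consultation,consultation,37,37
Germany,cabozantinib,laboratory,laboratory_panel,27,14
Germany,cabozantinib,imaging,imaging_mri_ct_mean,93,93
Germany,cabozantinib,ae,ae_total,682,139
Germany,BSC,drug,none,0,0
Germany,BSC,consultation,consultation,37,37
Germany,BSC,laboratory,laboratory_panel,27,14
Germany,BSC,imaging,imaging_mri_ct_mean,93,93
Germany,BSC,ae,ae_total,213,52
United States,cabozantinib,drug,cabozantinib,21581,21581
United States,cabozantinib,consultation,consultation,110,75
United States,cabozantinib,laboratory,laboratory_panel,110,55
United States,cabozantinib,imaging,imaging_mri_ct_mean,162,162
United States,cabozantinib,ae,ae_total,1673,645
United States,BSC,drug,none,0,0
United States,BSC,consultation,consultation,110,75
United States,BSC,laboratory,laboratory_panel,110,55
United States,BSC,imaging,imaging_mri_ct_mean,162,162
United States,BSC,ae,ae_total,557,166
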