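sample,assay,replicate,ct,detected
A_24h,miR,1,34.8,TRUE
A_24h,miR,2,35.0,TRUE
A_24h,miR,3,35.3,TRUE
A_24h,ref_mir,1,27.9,TRUE
A_24h,ref_mir,2,28.0,TRUE
A_24h,ref_mir,3,28.2,TRUE
A_24h,precursor,1,35.0,TRUE
A_24h,precursor,2,35.2,TRUE
A_24h,precursor,3,35.5,TRUE
A_24h,ref_gene,1,19.8,TRUE
A_24h,ref_gene,2,20.0,TRUE
A_24h,ref_gene,3,20.1,TRUE
G_24h,miR,1,34.6,TRUE
G_24h,miR,2,34.8,TRUE
G_24h,miR,3,35.1,TRUE
G_24h,ref_mir,1,27.8,TRUE
G_24h,ref_mir,2,28.0,TRUE
G_24h,ref_mir,3,28.3,TRUE
G_24h,precursor,1,35.4,TRUE
G_24h,precursor,2,35.59,TRUE
G_24h,precursor,3,35.8,TRUE
G_24h,ref_gene,1,19.9,TRUE
G_24h,ref_gene,2,20.0,TRUE
G_24h,ref_gene,3,20.2,TRUE
A_48h,miR,1,33.8,TRUE
A_48h,miR,2,34.0,TRUE
A_48h,miR,3,34.2,TRUE
A_48h,ref_mir,1,27.9,TRUE
A_48h,ref_mir,2,28.0,TRUE
A_48h,ref_mir,3,28.1,TRUE
A_48h,precursor,1,38.6,TRUE
A_48h,precursor,2,38.8,TRUE
A_48h,precursor,3,39.1,TRUE
A_48h,ref_gene,1,19.9,TRUE
A_48h,ref_gene,2,20.0,TRUE
A_48h,ref_gene,3,20.1,TRUE
G_48h,miR,1,33.6,TRUE
G_48h,miR,2,33.8,TRUE
G_48h,miR,3,34.0,TRUE
G_48h,ref_mir,1,27.9,TRUE
G_48h,ref_mir,2,28.0,TRUE
G_48h,ref_mir,3,28.2,TRUE
G_48h,precursor,1,40.1,TRUE
G_48h,precursor,2,40.37,TRUE
G_48h,precursor,3,40.6,TRUE
G_48h,ref_gene,1,19.8,TRUE
G_48h,ref_gene,2,20.0,TRUE
G_48h,ref_gene,3,20.3,TRUE
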