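# Regulatory-grouping rule table: one row per printed flow.
# Columns: per-layer state (methylation, rna, protein), protein detection
# substate, and the cluster label under each Regulation Grouping scheme
# (RG2 Changes, RG3 Protein, RG4 Detection).
# The "No Change" detection value on the all-No-Change row is the protein-layer
# catch-all; the loader expands it to any NoChange substate without an explicit row.
methylation	rna	protein	detection	rg2	rg3	rg4
Hypermethylation	DOWN	DOWN	DOWN	MDS	MDS	MDS
Hypermethylation	No Change	DOWN	DOWN	TMDS	TMDS	TMDS
Hypermethylation	UP	DOWN	DOWN	TPDE + TMDS	TMDS	TPDE + TMDS
Hypermethylation	DOWN	No Change	Not detected	MDS + TMDE	MDS	MDS
Hypermethylation	No Change	No Change	Not detected	None	None	None
Hypermethylation	UP	No Change	Not detected	TPDE + TMDS	TPDE	TPDE
Hypermethylation	DOWN	No Change	Not significant	MDS + TMDE	None	MDS + TMDE
Hypermethylation	No Change	No Change	Not significant	None	None	None
Hypermethylation	UP	No Change	Not significant	TPDE + TMDS	None	TPDE + TMDS
Hypermethylation	DOWN	No Change	Significant negative	MDS + TMDE	MDS	MDS
Hypermethylation	No Change	No Change	Significant negative	None	None	None
Hypermethylation	UP	No Change	Significant negative	TPDE + TMDS	TMDS	TPDE + TMDS
Hypermethylation	DOWN	No Change	Significant positive	MDS + TMDE	TMDE	MDS + TMDE
Hypermethylation	No Change	No Change	Significant positive	None	None	None
Hypermethylation	UP	No Change	Significant positive	TPDE + TMDS	TPDE	TPDE
Hypermethylation	DOWN	UP	UP	MDS + TMDE	TMDE	MDS + TMDE
Hypermethylation	No Change	UP	UP	TMDE	TMDE	TMDE
Hypermethylation	UP	UP	UP	TPDE	TPDE	TPDE
Hypomethylation	DOWN	DOWN	DOWN	TPDS	TPDS	TPDS
Hypomethylation	No Change	DOWN	DOWN	TMDS	TMDS	TMDS
Hypomethylation	UP	DOWN	DOWN	MDE + TMDS	TMDS	MDE + TMDS
Hypomethylation	DOWN	No Change	Not detected	TPDS + TMDE	TPDS	TPDS
Hypomethylation	No Change	No Change	Not detected	None	None	None
Hypomethylation	UP	No Change	Not detected	MDE + TMDS	MDE	MDE
Hypomethylation	DOWN	No Change	Not significant	TPDS + TMDE	None	TPDS + TMDE
Hypomethylation	No Change	No Change	Not significant	None	None	None
Hypomethylation	UP	No Change	Not significant	MDE + TMDS	None	MDE + TMDS
Hypomethylation	DOWN	No Change	Significant negative	TPDS + TMDE	TPDS	TPDS
Hypomethylation	No Change	No Change	Significant negative	None	None	None
Hypomethylation	UP	No Change	Significant negative	MDE + TMDS	TMDS	MDE + TMDS
Hypomethylation	DOWN	No Change	Significant positive	TPDS + TMDE	TMDE	TPDS + TMDE
Hypomethylation	No Change	No Change	Significant positive	None	None	None
Hypomethylation	UP	No Change	Significant positive	MDE + TMDS	MDE	MDE
Hypomethylation	DOWN	UP	UP	TPDS + TMDE	TMDE	TPDS + TMDE
Hypomethylation	No Change	UP	UP	TMDE	TMDE	TMDE
Hypomethylation	UP	UP	UP	MDE	MDE	MDE
No Change	DOWN	DOWN	DOWN	TPDS	TPDS	TPDS
No Change	No Change	DOWN	DOWN	TMDS	TMDS	TMDS
No Change	UP	DOWN	DOWN	TPDE + TMDS	TMDS	TPDE + TMDS
No Change	No Change	No Change	No Change	None	None	None
No Change	DOWN	No Change	Not detected	TPDS + TMDE	TPDS	TPDS
No Change	No Change	No Change	Not detected	None	None	None
No Change	UP	No Change	Not detected	TPDE + TMDS	TPDE	TPDE
No Change	DOWN	No Change	Not significant	TPDS + TMDE	None	TPDS + TMDE
No Change	No Change	No Change	Not significant	None	None	None
No Change	UP	No Change	Not significant	TPDE + TMDS	None	TPDE + TMDS
No Change	DOWN	No Change	Significant negative	TPDS + TMDE	TPDS	TPDS
No Change	UP	No Change	Significant negative	TPDE + TMDS	TMDS	TPDE + TMDS
No Change	DOWN	No Change	Significant positive	TPDS + TMDE	TMDE	TPDS + TMDE
No Change	UP	No Change	Significant positive	TPDE + TMDS	TPDE	TPDE
No Change	DOWN	UP	UP	TPDS + TMDE	TMDE	TPDS + TMDE
No Change	No Change	UP	UP	TMDE	TMDE	TMDE
No Change	UP	UP	UP	TPDE	TPDE	TPDE
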