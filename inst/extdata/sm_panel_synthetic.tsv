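# Representative 74-SM panel across the 9 assay genes; placeholder
# thresholds (lower/high confidence) -- calibrate before real use.
sm_id	gene	lower_threshold	high_threshold
BRAF:p.V600E:c.1799T>A	BRAF	4	6
BRAF:p.V600K	BRAF	4	6
BRAF:p.V600R	BRAF	4	6
KRAS:p.G12D/V:c.35G>A/T	KRAS	4	6
KRAS:p.G12C	KRAS	4	6
KRAS:p.G12A	KRAS	4	6
KRAS:p.G12S	KRAS	4	6
KRAS:p.G12R	KRAS	4	6
KRAS:p.G13D	KRAS	4	6
KRAS:p.Q61H	KRAS	4	6
KRAS:p.Q61L	KRAS	4	6
KRAS:p.Q61R	KRAS	4	6
KRAS:p.A146T	KRAS	4	6
EGFR:p.L858R	EGFR	4	6
EGFR:p.T790M	EGFR	4	6
EGFR:p.G719S	EGFR	4	6
EGFR:p.G719A	EGFR	4	6
EGFR:p.G719C	EGFR	4	6
EGFR:p.L861Q	EGFR	4	6
EGFR:p.S768I	EGFR	4	6
EGFR:p.E709K	EGFR	4	6
EGFR:p.E746_A750del	EGFR	4	6
EGFR:p.A767_V769dup	EGFR	4	6
IDH1:p.R132H	IDH1	4	6
IDH1:p.R132C	IDH1	4	6
IDH1:p.R132S	IDH1	4	6
IDH1:p.R132G	IDH1	4	6
IDH1:p.R132L	IDH1	4	6
IDH2:p.R140Q	IDH2	4	6
IDH2:p.R140W	IDH2	4	6
IDH2:p.R172K	IDH2	4	6
IDH2:p.R172M	IDH2	4	6
PTEN:p.R130G	PTEN	4	6
PTEN:p.R130Q	PTEN	4	6
PTEN:p.R173C	PTEN	4	6
PTEN:p.R233*	PTEN	4	6
PTEN:p.K267Rfs*9	PTEN	4	6
PTEN:p.T319*	PTEN	4	6
PTEN:p.R335*	PTEN	4	6
PTEN:p.C124S	PTEN	4	6
PIK3CA:p.E542K	PIK3CA	4	6
PIK3CA:p.E545K	PIK3CA	4	6
PIK3CA:p.E545Q	PIK3CA	4	6
PIK3CA:p.Q546K	PIK3CA	4	6
PIK3CA:p.H1047R	PIK3CA	4	6
PIK3CA:p.H1047L	PIK3CA	4	6
PIK3CA:p.C420R	PIK3CA	4	6
PIK3CA:p.N345K	PIK3CA	4	6
PIK3CA:p.G1049R	PIK3CA	4	6
PIK3CA:p.M1043I	PIK3CA	4	6
NRAS:p.G12D	NRAS	4	6
NRAS:p.G12S	NRAS	4	6
NRAS:p.G12C	NRAS	4	6
NRAS:p.G13D	NRAS	4	6
NRAS:p.G13R	NRAS	4	6
NRAS:p.G13V	NRAS	4	6
NRAS:p.Q61K	NRAS	4	6
NRAS:p.Q61L	NRAS	4	6
NRAS:p.Q61R	NRAS	4	6
TP53:p.R175H	TP53	4	6
TP53:p.G245S	TP53	4	6
TP53:p.R248Q	TP53	4	6
TP53:p.R248W	TP53	4	6
TP53:p.R249S	TP53	4	6
TP53:p.R273C	TP53	4	6
TP53:p.R273H	TP53	4	6
TP53:p.R282W	TP53	4	6
TP53:p.Y220C	TP53	4	6
TP53:p.R213*:c.637C>T	TP53	4	6
TP53:p.V157F	TP53	4	6
TP53:p.H179R	TP53	4	6
TP53:p.C176F	TP53	4	6
TP53:p.R337C	TP53	4	6
TP53:p.P151S	TP53	4	6
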