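item_id	cue_id	kind	pattern	entity	gate	sections	min_sentences
1a	1a-title-phrase	regex	(?i)randomi[sz]ed[A-Za-z ,-]*\b(trial|study)				1
1a	1a-controlled	regex	(?i)randomi[sz]ed[ ,]+controlled				1
1b	1b-structured-label	regex	(?i)^(background|objectives?|methods|design|results|findings|conclusions?|interpretation)\s*:			ABSTRACT	2
2b	2b-objective	lemma	objective				1
2b	2b-aim	lemma	aim				1
2b	2b-hypothesis	lemma	hypothesis				1
2b	2b-infinitive	regex	(?i)\bwe (assessed|aimed|sought)|to (determine|evaluate|assess) whether|to compare the effect				1
3a	3a-parallel	lemma	parallel		trial;study;design;group		1
3a	3a-crossover	lemma	crossover		trial;study;design;group		1
3a	3a-factorial	lemma	factorial		trial;study;design;group		1
3a	3a-design-regex	regex	(?i)(parallel|crossover|factorial|multicent(er|re))[- ]group				1
3b	3b-protocol-change	lemma	protocol		amendment;amend;change;modify;modification		1
4a	4a-eligibility	lemma	eligibility				1
4a	4a-eligible	lemma	eligible				1
4a	4a-inclusion	lemma	inclusion criterion				1
4a	4a-exclusion	lemma	exclusion criterion				1
4b	4b-site	lemma	site	LOCATION|ORG			1
4b	4b-setting	lemma	setting	LOCATION|ORG			1
4b	4b-center	lemma	center	LOCATION|ORG			1
4b	4b-hospital	lemma	hospital	LOCATION|ORG			1
4b	4b-clinic	lemma	clinic	LOCATION|ORG			1
4b	4b-recruit	lemma	recruit	LOCATION|ORG			1
5	5-receive	lemma	receive		group;arm;vs;versus		1
5	5-administer	lemma	administer		group;arm;vs;versus		1
5	5-dose	lemma	dose		group;arm;vs;versus		1
5	5-placebo	lemma	placebo		group;arm;vs;versus		1
5	5-intervention	lemma	intervention		group;arm;vs;versus		1
6a	6a-primary-outcome	lemma	primary outcome				1
6a	6a-secondary-outcome	regex	(?i)secondary outcomes? (included|consisted|were (assessed|defined|measured))				1
6a	6a-endpoint	regex	(?i)(primary|secondary) (efficacy )?end ?point				1
6b	6b-outcome-amended	lemma	outcome		amend;amendment		1
6b	6b-changes-to-outcome	regex	(?i)changes? to (the )?(trial )?outcomes?				1
7a	7a-sample-size	lemma	sample size	COUNT|PERCENTAGE			1
7a	7a-power	lemma	power	PERCENTAGE			1
7b	7b-interim	lemma	interim				1
7b	7b-stopping-rule	regex	(?i)stopping (rule|guideline|boundar)				1
7b	7b-dmc	lemma	data monitoring				1
8a	8a-computer	regex	(?i)computer[- ]generated				1
8a	8a-random-number	lemma	random number				1
8a	8a-rand-list	regex	(?i)randomi[sz]ation (list|schedule)				1
8a	8a-sequence	regex	(?i)(allocation )?sequence was (computer[- ])?generated				1
8b	8b-block	lemma	block		randomization;randomize;randomly;random		1
8b	8b-stratified	lemma	stratify		randomization;randomize;randomly;random		1
8b	8b-stratification	lemma	stratification		randomization;randomize;randomly;random		1
8b	8b-minimization	lemma	minimization				1
8b	8b-permuted	lemma	permute		randomization;randomize;randomly;random		1
9	9-conceal	lemma	conceal				1
9	9-concealment	lemma	concealment				1
9	9-envelope	lemma	sealed envelope				1
9	9-central	regex	(?i)central(i[sz]ed)? randomi[sz]ation				1
9	9-opaque	lemma	opaque				1
9	9-ivrs	regex	(?i)interactive (voice|web)[- ]response				1
10	10-pharmacist	lemma	pharmacist		enroll;assign;generate		1
10	10-coordinator	lemma	coordinator		enroll;assign;generate		1
11a	11a-blind	lemma	blind		participant;patient;investigator;assessor;clinician;personnel;care		1
11a	11a-mask	lemma	mask		participant;patient;investigator;assessor;clinician;personnel;care		1
11a	11a-open-label	regex	(?i)open[- ]label				1
11b	11b-identical	lemma	identical		placebo;appearance;taste;tablet;capsule		1
11b	11b-matching	lemma	match		placebo;appearance;taste;tablet;capsule		1
12a	12a-itt	regex	(?i)intention[- ]to[- ]treat				1
12a	12a-logrank	regex	(?i)log[- ]rank				1
12a	12a-chisq	regex	(?i)chi[- ]square				1
12a	12a-ttest	regex	(?i)\bt[- ]test|student'?s t				1
12a	12a-km	regex	(?i)kaplan[- ]meier				1
12a	12a-mixed	regex	(?i)mixed([- ]effects?)? model				1
12a	12a-cox	regex	(?i)cox (proportional|regression)				1
12a	12a-regression	lemma	regression				1
12a	12a-ancova	regex	(?i)analysis of (covariance|variance)				1
12b	12b-subgroup	lemma	subgroup;analysis			METHODS	1
12b	12b-sensitivity	lemma	sensitivity;analysis			METHODS	1
12b	12b-adjusted	lemma	adjust;analysis			METHODS	1
13a	13a-randomly-assigned	regex	(?i)randomly assigned	COUNT			1
13a	13a-were-randomized	regex	(?i)were randomi[sz]ed	COUNT			1
13b	13b-lost-fu	regex	(?i)lost to follow[- ]up	COUNT			1
13b	13b-withdrew	lemma	withdraw	COUNT			1
13b	13b-discontinued	lemma	discontinue	COUNT			1
14a	14a-enroll-dates	lemma	enroll	DATE_RANGE			1
14a	14a-recruit-dates	lemma	recruit	DATE_RANGE			1
14a	14a-enrollment-dates	lemma	enrollment	DATE_RANGE			1
14a	14a-recruitment-dates	lemma	recruitment	DATE_RANGE			1
14b	14b-stopped	regex	(?i)trial (was )?(stopped|ended|terminated)				1
14b	14b-early	regex	(?i)(stopped|terminated) early				1
14b	14b-completed-fu	regex	(?i)completed (the )?follow[- ]up				1
14b	14b-final-visit	regex	(?i)final (study )?visit				1
15	15-baseline-chars	lemma	baseline;characteristic				1
15	15-table1	regex	(?i)table 1		baseline;demographic;characteristic		1
16	16-included-analysis	regex	(?i)included in the (primary |final )?analysis	COUNT			1
16	16-analyzed	regex	(?i)were analy[sz]ed	COUNT			1
17a	17a-difference	lemma	difference	CONFIDENCE_INTERVAL			1
17a	17a-ratio	lemma	ratio	CONFIDENCE_INTERVAL			1
17a	17a-hazard	lemma	hazard	CONFIDENCE_INTERVAL			1
17a	17a-odds	lemma	odds	CONFIDENCE_INTERVAL			1
17a	17a-mean	lemma	mean	CONFIDENCE_INTERVAL			1
18	18-posthoc	lemma	post hoc			RESULTS	1
18	18-exploratory	lemma	exploratory			RESULTS	1
18	18-ancillary	lemma	ancillary			RESULTS	1
19	19-adverse	lemma	adverse				1
19	19-harm	lemma	harm				1
19	19-toxicity	lemma	toxicity				1
19	19-side-effect	lemma	side effect				1
20	20-limitation	lemma	limitation				1
20	20-caveat	lemma	caveat				1
20	20-imprecision	lemma	imprecision				1
21	21-generalizability	lemma	generalizability				1
21	21-applicability	lemma	applicability				1
21	21-external-validity	lemma	external validity				1
23	23-registry-id	entity	REGISTRY_ID				1
24	24-protocol-access	lemma	protocol		available;publish;appendix;supplement;access		1
25	25-funded	lemma	fund				1
25	25-grant	lemma	grant				1
25	25-supported-by	regex	(?i)supported by				1
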