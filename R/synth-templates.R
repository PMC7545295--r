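# Template bank for the synthetic RCT-manuscript generator. Templates are
# parameterized (drug names, counts, dates, registry ids drawn from seeded
# pools) so no two fixtures are textually identical. Each template realizes
# exactly one sentence (no internal sentence boundaries). The distractor
# bank holds near-miss sentences ("assigned a study identification number")
# that must not trigger any detector; they operationalize the negative
# triage group.

SYNTH_POOLS <- list(
  drug = c("almorextan", "bevoprazole", "cartilumab", "dexofenine",
           "epralastat", "fornastine", "galvedon", "hydrazoline",
           "ibrenoxib", "jasperium"),
  comparator = c("placebo", "usual care", "standard therapy", "sham treatment"),
  condition = c("refractory angina pectoris", "hand osteoarthritis",
                "chronic heart failure", "persistent asthma",
                "major depressive disorder", "type 2 diabetes",
                "chronic migraine", "rheumatoid arthritis"),
  outcome = c("treadmill exercise time", "pain intensity score",
              "forced expiratory volume", "symptom severity score",
              "six-minute walking distance", "glycated hemoglobin level"),
  org = c("National Institutes of Health", "Medical Research Council",
          "Wellcome Trust", "British Heart Foundation",
          "National Cancer Institute", "Canadian Institutes of Health Research"),
  country = c("Canada", "Germany", "France", "Australia", "Netherlands",
              "Sweden", "United Kingdom", "United States"),
  city = c("Boston", "Toronto", "London", "Amsterdam", "Stockholm", "Berlin"),
  month = c("January", "February", "March", "April", "May", "June", "July",
            "August", "September", "October", "November", "December")
)

# draw one parameter set for a manuscript (assumes RNG already seeded)
sample_params <- function() {
  pick <- function(x) x[sample.int(length(x), 1L)]
  n_arm <- sample(60:240, 1L)
  p <- list(
    drug = pick(SYNTH_POOLS$drug),
    comp = pick(SYNTH_POOLS$comparator),
    cond = pick(SYNTH_POOLS$condition),
    outcome = pick(SYNTH_POOLS$outcome),
    outcome2 = pick(SYNTH_POOLS$outcome),
    org1 = pick(SYNTH_POOLS$org),
    org2 = pick(SYNTH_POOLS$org),
    country1 = pick(SYNTH_POOLS$country),
    country2 = pick(SYNTH_POOLS$country),
    city = pick(SYNTH_POOLS$city),
    ratio = pick(c("1:1", "2:1", "1:1:1")),
    n_arm = n_arm,
    n_total = 2L * n_arm,
    n_screen = 2L * n_arm + sample(20:80, 1L),
    n_treated = 2L * n_arm - sample(1:6, 1L),
    n_analyzed = 2L * n_arm - sample(4:12, 1L),
    dose = sample(c(10L, 25L, 50L, 100L, 200L, 400L), 1L),
    weeks = sample(c(8L, 12L, 24L, 52L), 1L),
    power = sample(c(80L, 85L, 90L), 1L),
    effect = sample(2:8, 1L),
    sites = sample(4:30, 1L),
    block = sample(c(4L, 6L, 8L), 1L),
    age_lo = sample(18:45, 1L),
    age_hi = sample(65:85, 1L),
    lost = sample(2:9, 1L),
    wd = sample(1:6, 1L),
    ae1 = sample(5:25, 1L),
    ae2 = sample(5:25, 1L),
    y1 = sample(2009:2015, 1L),
    m1 = pick(SYNTH_POOLS$month),
    m2 = pick(SYNTH_POOLS$month),
    nct = sprintf("NCT%08d", sample.int(99999999L, 1L)),
    isrctn = sprintf("ISRCTN%08d", sample.int(99999999L, 1L)),
    pval = sprintf("0.%03d", sample(1:49, 1L))
  )
  p$y2 <- p$y1 + sample(1:4, 1L)
  p$ci_lo <- p$effect - sample(1:2, 1L)
  p$ci_hi <- p$effect + sample(2:5, 1L)
  p
}

tpl <- function(s, p) {
  for (key in names(p)) {
    s <- gsub(paste0("{", key, "}"), as.character(p[[key]]), s, fixed = TRUE)
  }
  # realized sentences must start with an uppercase letter or digit so the
  # sentence splitter sees the same boundaries the truth coordinates assume
  sub("^([a-z])", "\\U\\1", s, perl = TRUE)
}

# titles: variants that do / do not identify the study as randomized
TITLES_RANDOMIZED <- c(
  "Effect of {drug} Compared With {comp} in {cond}: A Randomised Controlled Trial",
  "{drug} versus {comp} for {cond}: A Randomized Trial",
  "A Double-Blind Randomised Study of {drug} in Patients With {cond}"
)
TITLES_PLAIN <- c(
  "Effect of {drug} on {outcome} in Patients With {cond}",
  "{drug} for the Treatment of {cond}: Principal Results",
  "Long-Term Outcomes of {drug} Therapy in {cond}"
)

ABSTRACT_STRUCTURED <- c(
  "Background: {cond} is associated with substantial morbidity despite available therapy.",
  "Methods: Adults with {cond} were randomly assigned to {drug} or {comp} for {weeks} weeks.",
  "Results: The primary analysis favoured {drug} over {comp}.",
  "Conclusions: {drug} improved {outcome} in patients with {cond}."
)
ABSTRACT_PLAIN <- c(
  "We report the principal findings of a clinical study of {drug} in {cond}.",
  "The treatment was well tolerated and the main findings are described below."
)

# per-item template variants; each entry: sentence template + home section
ITEM_TEMPLATES <- list(
  "2b" = list(section = "INTRODUCTION", variants = c(
    "The objective of this trial was to determine whether {drug} improves {outcome} in patients with {cond}.",
    "We aimed to compare the effect of {drug} and {comp} on {outcome}.",
    "Our hypothesis was that {drug} would reduce {outcome} relative to {comp}.")),
  "3a" = list(section = "METHODS", variants = c(
    "The study was designed as a parallel-group, double-blind trial in which participants were allocated in a {ratio} ratio.",
    "We conducted a multicentre, parallel-group randomised trial with a {ratio} allocation ratio."),
    noratio = "The study was designed as a parallel-group, double-blind trial comparing {drug} with {comp}."),
  "3b" = list(section = "METHODS", variants = c(
    "An important amendment to the protocol was approved by the ethics committee after the trial commenced, and the reasons were documented.",
    "After trial commencement, the protocol was modified to clarify the dosing schedule, with reasons recorded.")),
  "4a" = list(section = "METHODS", variants = c(
    "Patients were eligible if they were aged {age_lo} to {age_hi} years and had documented {cond} for at least 6 months.",
    "Key inclusion criteria were age {age_lo} years or older and a confirmed diagnosis of {cond}; exclusion criteria included pregnancy and prior surgery.")),
  "4b" = list(section = "METHODS", variants = c(
    "Participants were recruited at {sites} hospital sites in {country1} and {country2}.",
    "The study was conducted at {sites} academic medical centers in {city}, {country1}.")),
  "5" = list(section = "METHODS", variants = c(
    "Patients in the {drug} group received oral {drug} {dose} mg twice daily for {weeks} weeks, and those in the control group received matching-strength tablets of inert formulation.",
    "The intervention group received {drug} administered subcutaneously every 4 weeks, whereas the comparison arm received {comp}.")),
  "6a" = list(section = "METHODS", variants = c(
    "The primary outcome was the change from baseline in {outcome} at {weeks} weeks.",
    "The prespecified secondary outcomes included {outcome2} and quality of life, assessed at each study visit.")),
  "6b" = list(section = "METHODS", variants = c(
    "The secondary outcomes were amended after the trial commenced because of slow accrual, with reasons reported to the steering committee.",
    "Changes to the trial outcomes were made after commencement and are described in the statistical analysis plan.")),
  "7a" = list(section = "METHODS", variants = c(
    "We calculated that a sample size of {n_total} patients would provide {power}% power to detect a {effect}-point difference at a two-sided alpha of 0.05.",
    "The target sample size of {n_total} participants gave the trial {power}% power at a significance level of 0.05.")),
  "7b" = list(section = "METHODS", variants = c(
    "One interim analysis was planned, and an independent data monitoring committee applied prespecified stopping guidelines.",
    "No formal interim analyses were planned and there were no early stopping rules.")),
  "8a" = list(section = "METHODS", variants = c(
    "The random allocation sequence was computer-generated with a random number generator and held centrally.",
    "An independent statistician generated the randomisation list using statistical software.")),
  "8b" = list(section = "METHODS", variants = c(
    "Randomisation was stratified by study centre with permuted blocks of {block}.",
    "We used blocked randomization with a block size of {block}, stratified by sex.")),
  "9" = list(section = "METHODS", variants = c(
    "Allocation was concealed by means of sequentially numbered, opaque, sealed envelopes.",
    "Treatment assignments were concealed through a central interactive web-response system until interventions were assigned.")),
  "10" = list(section = "METHODS", variants = c(
    "A study coordinator enrolled participants, and an independent pharmacist assigned them to the interventions.",
    "The trial pharmacist generated the allocation schedule and assigned participants to the study arms according to the sequence.")),
  "11a" = list(section = "METHODS", variants = c(
    "Participants, investigators, and outcome assessors were blinded to treatment assignment throughout the trial.",
    "Patients and clinicians were masked to group allocation until the database was locked.")),
  "11b" = list(section = "METHODS", variants = c(
    "The placebo tablets were identical in appearance and taste to the active {drug} tablets.",
    "Active and control injections were matched for appearance, volume, and packaging.")),
  "12a" = list(section = "METHODS", variants = c(
    "All efficacy analyses followed the intention-to-treat principle, and between-group differences were compared with a mixed-effects model.",
    "Time-to-event outcomes were analysed with the Kaplan-Meier method and compared with the log-rank test.")),
  "12b" = list(section = "METHODS", variants = c(
    "Prespecified subgroup analyses were performed according to age and sex, with adjustment for baseline {outcome}.",
    "Sensitivity analyses excluding patients with protocol deviations were conducted as additional analyses.")),
  "13a" = list(section = "RESULTS", variants = c(
    "Of the {n_screen} patients who underwent screening, {n_arm} were randomly assigned to receive {drug} and {n_arm} to receive {comp}, and {n_treated} received the intended treatment.",
    "A total of {n_arm} participants were randomised to {drug} and {n_arm} to {comp}, of whom {n_treated} began the assigned regimen.")),
  "13b" = list(section = "RESULTS", variants = c(
    "After randomisation, {lost} patients in each group were lost to follow-up and {wd} withdrew consent.",
    "{lost} participants discontinued the assigned regimen before week {weeks} and {wd} withdrew consent.")),
  "14a" = list(section = "RESULTS", variants = c(
    "Patients were enrolled between {m1} {y1} and {m2} {y2} at the participating sites.",
    "Recruitment took place from {m1} {y1} to {m2} {y2}, and the last follow-up assessment occurred one year later.")),
  "14b" = list(section = "RESULTS", variants = c(
    "The trial ended as planned when the last randomised patient completed the final study visit.",
    "The trial was stopped early after a planned review because of slower than expected accrual.")),
  "15" = list(section = "RESULTS", variants = c(
    "Baseline demographic and clinical characteristics were similar in the two groups and are shown in Table 1.",
    "The baseline characteristics of the participants are presented in Table 1.")),
  "16" = list(section = "RESULTS", variants = c(
    "In total, {n_analyzed} and {n_arm} patients, respectively, were included in the primary analysis according to their original assigned groups.",
    "All {n_analyzed} participants with at least one follow-up measurement were analysed according to the original assignment.")),
  "17a" = list(section = "RESULTS", variants = c(
    "The mean difference in {outcome} between groups was {effect} points (95% CI, {ci_lo} to {ci_hi}; P={pval}).",
    "The hazard ratio for death from any cause was 0.82 (95% confidence interval, 0.68 to 0.97).")),
  "18" = list(section = "RESULTS", variants = c(
    "Results of prespecified exploratory analyses of ancillary end points are reported in the supplementary material.",
    "Post hoc analyses distinguishing prespecified from exploratory comparisons yielded consistent findings.")),
  "19" = list(section = "RESULTS", variants = c(
    "Serious adverse events occurred in {ae1} patients in the {drug} group and {ae2} patients in the control group.",
    "The most common side effects were headache and nausea, and no treatment-related toxicity of grade 3 or higher was observed.")),
  "20" = list(section = "DISCUSSION", variants = c(
    "This trial has several limitations, including imprecision arising from the modest number of events.",
    "An important limitation is that adherence was self-reported, which may have introduced measurement error.")),
  "21" = list(section = "DISCUSSION", variants = c(
    "The generalisability of these findings may be limited to patients with moderate {cond}.",
    "The applicability of the results to older adults and to community practice is uncertain.")),
  "23" = list(section = "OTHER_INFO", variants = c(
    "This trial is registered with ClinicalTrials.gov, number {nct}.",
    "The study was prospectively registered in the ISRCTN registry ({isrctn}).")),
  "24" = list(section = "OTHER_INFO", variants = c(
    "The full trial protocol is available in Supplement 1 and from the corresponding author.",
    "The trial protocol has been published and can be accessed on the journal website.")),
  "25" = list(section = "OTHER_INFO", variants = c(
    "This trial was funded by the {org1} and the {org2}.",
    "The study was supported by a grant from the {org1}; the funder had no role in the trial conduct."))
)

# near-miss distractor bank, keyed by home section
DISTRACTORS <- list(
  INTRODUCTION = c(
    "{cond} affects millions of adults worldwide and is a leading cause of reduced quality of life.",
    "Previous observational reports have described conflicting findings for this class of therapy.",
    "Current clinical practice varies widely between regions and providers.",
    "Optimal medical therapy alone leaves many patients with persistent symptoms."),
  METHODS = c(
    "Patients were assigned a study identification number at the screening visit.",
    "Study visits took place at weeks 2, 6, and {weeks}, and data were entered into an electronic case report form.",
    "The institutional review board at each participating institution approved the study, and all patients provided written informed consent.",
    "Adherence was monitored by pill counts at each visit."),
  RESULTS = c(
    "The mean age of the participants was 63 years, and 48% were women.",
    "Median follow-up was {weeks} weeks.",
    "Treatment adherence exceeded 92% in both groups.",
    "Vital signs remained stable over the course of the study."),
  DISCUSSION = c(
    "Our findings are consistent with earlier reports of similar interventions.",
    "Further research is needed to clarify the mechanisms underlying the observed benefit.",
    "The results add to a growing body of evidence favouring early treatment."),
  OTHER_INFO = c(
    "We thank the patients and their families for their participation.",
    "The authors declare no competing interests.")
)

REFERENCES_BANK <- c(
  "1. Smith J, Jones K. Long-term outcomes of revascularization in stable coronary disease. N Engl J Med. 2015;372:1204-1212.",
  "2. Brown A, Lee C. A randomised trial of spinal cord stimulation in refractory angina. Lancet. 2016;388:456-464.",
  "3. Garcia M, Chen W. Sample size determination for cluster designs. Stat Med. 2014;33:301-315.",
  "4. Patel R, Novak T. Blinding and allocation concealment in surgical trials. BMJ. 2018;360:k121."
)

FIGURE1_CAPTION <- "Enrolment, randomisation, and follow-up of the study participants in the trial flow diagram."
TABLE1_CAPTION <- "Baseline demographic and clinical characteristics of the study groups."
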