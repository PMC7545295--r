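# Organization gazetteer: funders, agencies, sponsors commonly named in trial reports.
World Health Organization
WHO
National Institutes of Health
NIH
National Cancer Institute
National Heart, Lung, and Blood Institute
National Institute for Health Research
Medical Research Council
Wellcome Trust
Cancer Research UK
British Heart Foundation
American Heart Association
American Cancer Society
Canadian Institutes of Health Research
European Commission
Bill and Melinda Gates Foundation
Howard Hughes Medical Institute
Food and Drug Administration
European Medicines Agency
Centers for Disease Control and Prevention
Patient-Centered Outcomes Research Institute
Agency for Healthcare Research and Quality
National Science Foundation
Deutsche Forschungsgemeinschaft
Pfizer
Novartis
Roche
AstraZeneca
GlaxoSmithKline
Merck
Sanofi
Bayer
Eli Lilly
Bristol-Myers Squibb
Boehringer Ingelheim
Amgen
Gilead Sciences
Johnson & Johnson
Takeda
Abbott
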