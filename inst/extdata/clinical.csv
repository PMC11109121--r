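"patient_id","sex","age","smoking","stage_at_sampling","mutations","drug","line","recist_label","tumor_change_pct","notes"
"200","male",68,"current","IVB (T4N3M1c)","EGFR exon19 deletion","afatinib",1,"PR","","first-line TKI started at sampling"
"224","male",64,"ex","IVB (T4N3M1c)","EGFR exon19 deletion;T790M","afatinib",1,"PD","","initial PR; progression with T790M before sampling"
"224","male",64,"ex","IVB (T4N3M1c)","EGFR exon19 deletion;T790M","osimertinib",2,"PD","","progression before sampling"
"240","female",56,"never","IVB (T4N3M1c)","EGFR exon19 deletion;T790M;ALK translocation","afatinib",1,"PD","","initial PR; progression before sampling"
"240","female",56,"never","IVB (T4N3M1c)","EGFR exon19 deletion;T790M;ALK translocation","osimertinib",3,"PD","","initial PR; progression with effusion before sampling"
"246","female",65,"ex","IVA (T4N1M1a)","EGFR exon19 deletion;T790M","afatinib",1,"PD","","initial PR; progression on day 555 before sampling"
"246","female",65,"ex","IVA (T4N1M1a)","EGFR exon19 deletion;T790M","osimertinib",2,"PR","","no progression for over 700 days"
"263","female",79,"never","IVB (T4N3M1c)","EGFR exon19 deletion;T790M","afatinib",1,"PD","","initial PR; progression with T790M before sampling"
"263","female",79,"never","IVB (T4N3M1c)","EGFR exon19 deletion;T790M","lazertinib",2,"NE","","inconsistent dosing; died of ARDS secondary to COVID-19"
"266","female",61,"never","IVA (T2aN0M1a)","EGFR exon19 deletion;exon20 insertion","afatinib",1,"PR","",""
"278","female",49,"never","IVB (TXN3M1c)","EGFR exon19 deletion;T790M","afatinib",1,"PD","","initial PR; progression with T790M before sampling"
"278","female",49,"never","IVB (TXN3M1c)","EGFR exon19 deletion;T790M","lazertinib",2,"PR","",""
"282","female",83,"never","IVB (TXN3M1c)","EGFR exon19 insertion;T790M","gefitinib",1,"PR","","near-complete response; relapse on day 1150"
"282","female",83,"never","IVB (TXN3M1c)","EGFR exon19 insertion;T790M","afatinib",2,"PD","","one month of treatment; progression confirmed before sampling"
"282","female",83,"never","IVB (TXN3M1c)","EGFR exon19 insertion;T790M","lazertinib",3,"PD","",""
"283","male",64,"ex","IVB (T4N3M1c)","EGFR exon21 L858R","afatinib",1,"PD","","second-generation TKI given was dacomitinib; initial PR then progression at sampling"
"305","male",97,"never","IVB (T4N0M1c)","EGFR exon21 L858R","afatinib",1,"PR","",""
"316","male",70,"ex","IVB (T1bN0M1c)","EGFR exon19 deletion","afatinib",1,"SD","-20","tumor decrease 20 percent; clinically sensitive"
"331","female",85,"never","IVA (T2bN2M1a)","EGFR exon21 L858R","afatinib",1,"SD","-10","tumor decrease 10 percent; follow-up CT showed reduced mass; clinically sensitive"
"334","male",62,"ex","IVA (T1bN0M1a)","EGFR exon19 deletion","afatinib",1,"PR","",""
"340","male",65,"ex","IVB (T4N3M1c)","EGFR exon19 deletion","afatinib",1,"PR","","PR before voluntary discontinuation; progression with effusion at sampling"
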