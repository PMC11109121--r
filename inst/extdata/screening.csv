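patient_id,drug,mode,call
200,afatinib,codrp,sensitive
224,afatinib,codrp,resistant
240,afatinib,codrp,resistant
246,afatinib,codrp,resistant
263,afatinib,codrp,resistant
266,afatinib,codrp,sensitive
278,afatinib,codrp,resistant
282,afatinib,codrp,resistant
283,afatinib,codrp,resistant
305,afatinib,codrp,sensitive
316,afatinib,codrp,sensitive
331,afatinib,codrp,resistant
334,afatinib,codrp,sensitive
340,afatinib,codrp,sensitive
200,osimertinib,codrp,sensitive
224,osimertinib,codrp,resistant
240,osimertinib,codrp,resistant
246,osimertinib,codrp,sensitive
263,osimertinib,codrp,sensitive
266,osimertinib,codrp,sensitive
278,osimertinib,codrp,sensitive
282,osimertinib,codrp,resistant
283,osimertinib,codrp,resistant
305,osimertinib,codrp,sensitive
316,osimertinib,codrp,sensitive
331,osimertinib,codrp,resistant
334,osimertinib,codrp,sensitive
340,osimertinib,codrp,sensitive
200,afatinib,auc,sensitive
224,afatinib,auc,resistant
240,afatinib,auc,sensitive
246,afatinib,auc,resistant
263,afatinib,auc,resistant
266,afatinib,auc,resistant
278,afatinib,auc,sensitive
282,afatinib,auc,resistant
283,afatinib,auc,resistant
305,afatinib,auc,sensitive
316,afatinib,auc,sensitive
331,afatinib,auc,resistant
334,afatinib,auc,sensitive
340,afatinib,auc,sensitive
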