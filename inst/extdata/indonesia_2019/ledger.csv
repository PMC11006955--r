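institution,from_stage,to_stage,amount,currency,note,external
BKKBN,ORIGIN,NATIONAL,252736,USD_thousands,state budget allocation,FALSE
BKKBN,NATIONAL,PROVINCIAL,225967,USD_thousands,,FALSE
BKKBN,PROVINCIAL,DISTRICT,153009,USD_thousands,,FALSE
BKKBN,DISTRICT,EXPENDITURE_PUBLIC,153009,USD_thousands,,FALSE
BKKBN,DISTRICT,EXPENDITURE_PRIVATE,0,USD_thousands,true zero: no BKKBN spending at private facilities,FALSE
Ministry of Health,ORIGIN,NATIONAL,14160,USD_thousands,,FALSE
Ministry of Health,NATIONAL,PROVINCIAL,14160,USD_thousands,,FALSE
Ministry of Health,PROVINCIAL,DISTRICT,14160,USD_thousands,,FALSE
Ministry of Health,DISTRICT,EXPENDITURE_PUBLIC,14160,USD_thousands,,FALSE
Ministry of Health,DISTRICT,EXPENDITURE_PRIVATE,0,USD_thousands,,FALSE
Ministry of Finance,ORIGIN,NATIONAL,185111,USD_thousands,special allocation and FP operational funds,FALSE
Ministry of Finance,NATIONAL,DISTRICT,185111,USD_thousands,bypasses the provincial level,FALSE
Ministry of Finance,DISTRICT,EXPENDITURE_PUBLIC,185111,USD_thousands,,FALSE
Ministry of Finance,DISTRICT,EXPENDITURE_PRIVATE,0,USD_thousands,,FALSE
Other ministries,ORIGIN,NATIONAL,258,USD_thousands,,FALSE
Other ministries,NATIONAL,EXPENDITURE_PUBLIC,258,USD_thousands,spent at national level,FALSE
Other ministries,NATIONAL,EXPENDITURE_PRIVATE,0,USD_thousands,,FALSE
JKN,ORIGIN,NATIONAL,2616,USD_thousands,government premium subsidy earmarked for FP,FALSE
JKN,NATIONAL,DISTRICT,2616,USD_thousands,,FALSE
JKN,DISTRICT,EXPENDITURE_PUBLIC,28198,USD_thousands,reimbursements exceed tracked budget (member premiums),FALSE
JKN,DISTRICT,EXPENDITURE_PRIVATE,602,USD_thousands,JKN-contracted private facilities,FALSE
UNFPA,ORIGIN,NATIONAL,163,USD_thousands,treated as public sector,FALSE
UNFPA,NATIONAL,EXPENDITURE_PUBLIC,163,USD_thousands,,FALSE
UNFPA,NATIONAL,EXPENDITURE_PRIVATE,0,USD_thousands,,FALSE
Other NGOs,ORIGIN,NATIONAL,7259,USD_thousands,,FALSE
Other NGOs,NATIONAL,EXPENDITURE_PUBLIC,0,USD_thousands,true zero,FALSE
Other NGOs,NATIONAL,EXPENDITURE_PRIVATE,7260,USD_thousands,printed amounts differ by one thousand (rounding),FALSE
Out-of-pocket Payment,ORIGIN,NATIONAL,244413,USD_thousands,household payments at point of care,FALSE
Out-of-pocket Payment,NATIONAL,EXPENDITURE_PUBLIC,49988,USD_thousands,OOP paid at public facilities,FALSE
Out-of-pocket Payment,NATIONAL,EXPENDITURE_PRIVATE,194425,USD_thousands,,FALSE
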