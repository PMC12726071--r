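CDR3_alpha,CDR3_beta,Epitope,Pathology,Source
CAVMDSNYQLIW,CASSEGGLGEQYF,5-OP-RU,Mycobacterium tuberculosis,SYN001
CAVRDSNYQLIW,CASSDRGNQPQHF,5-OP-RU,Mycobacterium tuberculosis,SYN002
CAVSLQDYKLSF,CASSEFGGTEAFF,5-OP-RU,Escherichia coli,SYN003
CAVKDSNYQLIW,,5-OP-RU,Salmonella enterica,SYN004
CAGQASQGNLIF,CASSIRSSYEQYF,M1 GILGFVFTL,Influenza A,SYN005
CAVSPGGGADGLTF,CASSLGGGNQPQHF,pp65 NLVPMVATV,Cytomegalovirus,SYN006
CILRDGRGGSYIPTF,CASSPGQGGYEQYF,BMLF1 GLCTLVAML,Epstein-Barr virus,SYN007
,CASSVGGGTDTQYF,Gliadin,Celiac disease,SYN008
CAASGGGSYIPTF,CASSFEGGQETQYF,Insulin B:9-23,Type 1 diabetes,SYN009
CAVNNNNDMRF,CASSQDNNNEQFF,Gliadin,Celiac disease,SYN010
CAVRGGGGNKLTF,,Spike YLQPRTFLL,SARS-CoV-2,SYN011
CAETRSRDYKLSF,CASSPTSGGYGYTF,EBNA3A FLRGRAYGL,Epstein-Barr virus,SYN012
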