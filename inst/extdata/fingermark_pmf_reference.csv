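condition,protein,observed_mz,sequence,ppm_reported
set_i,Dermcidin,1128.523,ENAGEDPGLAR,-4.7
set_i,Keratin type I cytoskeletal 9,1065.509,STMQELNSR,9.1
set_i,Keratin type I cytoskeletal 9,1157.588,QGVDADINGLR,-2.1
set_i,Keratin type I cytoskeletal 9,1791.724,GGSGGSYGGGGSGGGYGGGSGSR,-1.8
set_i,Filaggrin,1421.638,SESASRNHYGSAR,-9.4
set_i,Sortilin-related receptor,1232.595,IEVANPDGDFR,3.6
set_i,Calmodulin like protein 3,1874.849,EAFSLFDKDGDGCITTR,-5.2
set_ii,Dermcidin,725.392,GAVHDVK,-2.6
set_ii,Dermcidin,1128.524,ENAGEDPGLAR,-3.3
set_ii,Keratin type II cytoskeletal 1,1033.511,TLLEGEESR,-4.7
set_ii,Keratin type II cytoskeletal 1,1277.708,LALDLEIATYR,-1.6
set_ii,Keratin type I cytoskeletal 9,1157.590,QGVDADINGLR,-0.5
set_ii,Keratin type I cytoskeletal 9,1066.506,FEMEQNLR,7.1
set_ii,Filaggrin,1493.731,QGSHHKQARDSSR,-0.5
set_ii,Filaggrin,1513.728,QGSRHEQARDSSR,4.3
set_ii,Desmoplakin,1107.536,AEFQEEAKR,-5.9
set_ii,Protein Shroom 3,1201.604,SLADILDPDSR,-1.9
set_ii,Zinc a2 glycoprotein,1475.757,WEAEPVYVQRAK,-4.8
set_iii,Dermcidin,1128.522,ENAGEDPGLAR,-5.0
set_iii,Filaggrin,1513.728,QGSRHEQARDSSR,4.4
set_iii,Keratin type II cytoskeletal 1,1308.655,NKYEDEINKR,0.8
set_iii,Desmoplakin,1254.594,AITGFDDPFSGK,-5.2
set_iii,Desmoplakin,1818.990,IDKQIDFRLWDLEK,8.2
set_iii,Filamin B,1373.651,WCNEHLKCVNK,4.1
set_iii,Keratin type I cytoskeletal 10,1996.969,ELTTEIDNNIEQISSYK,-0.9
set_iii,Myosin-6,718.398,KGFPNR,-1.5
set_iv,Dermcidin,1128.530,ENAGEDPGLAR,2.0
set_iv,Keratin type I cytoskeletal 9,1791.737,GGSGGSYGGGGSGGGYGGGSGSR,5.5
set_iv,Keratin type I cytoskeletal 9,982.436,FSSSGGGGGGGR,2.7
set_iv,Desmoplakin,1254.593,AITGFDDPFSGK,-5.6
set_iv,Keratin type II cytoskeletal 1,1006.431,GGSGGGGGGSSGGR,1.5
set_iv,Keratin type II cytoskeletal 1,832.492,SISISVAR,3.5
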