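@synthread01
GATTTGTGGGCTCTATGCCTCCTTCGAATTTCTAACTGCAACCGTATACTCAAGTGCCTGGTATAATGGATCCAGCAGACCATTGAGTGGCGACCGGCAATCACATTTTGTTTGCAGTTACGCCTGAGCGAAGGGTATCTCGCACAAGAATGTCGGGAGGTGCAGCACAGAGCGCGAAGTTACAGTATCGTCGGACGCGTCAGCTTAACAGCTGCGCACC
+synthread01
/.-/6865354>AA4B@HAAOMROSKQTIQKPOVOSROOSNQSYLRRTTYONNMNKUPUQWTSRXPITSIVLRQRPWTMQLUTJRUPPPTLONTSILLQVZSURLRPVOLLUNQOJYSPUPPLPNQMMOSMRNQXNLSRPSLNXTTXRTULQ[VNERPNRXQQWONRJVZPUORSVVRTOTRTNOTUPNSOMSUVSTPUCIICEG=<>@<6:4)5320*/
@synthread02
AAGGGAATGCAACATGGCACCCTGTATTGCCTTAGATACGCTAAAGTGGCGGACACTTACGTGGATACTCACCGACGGCATTTATTACGAGCCTGTTCTTGGTAGCAAGTTGTTCTCCGCAAACGCAGTTGTATTTATTGCCTGCTTGGCGCTACAGCCCAGCGCCATTCAGTTGGATCAAGTATTAAGCGCGCAACCCA
+synthread02
-*.3*51977=<=<??DFJCJNO[SPTQOLPPTUTNOXXKMVPMOMQOSSOOQRWPPXSRTLOQMUTUUPMULQJPUSXLPLTNLQPPUOPTYQUOQRLZMPJPINPREPOTOQPULMSTRWPORMJQSPSNWSM]UVNVPPUOLVMORWOUPMQPSMNPMOQTNVPPLMRLPTMRMIQGCPO=FGD@F7:8<3,36++)
@synthread03
GATCTCGCTTCTTCGGTGCTAGGCGAATATTAAGTGGTTATTTACGCTCAAAGCCTGGCAATGCATGCGGGACAAGTAACTATCCATTTCACGGTCGCCCTACGTTTTACTTCAAATCTA
+synthread03
'%4./,10,.20;136759;8@;<;?>?BDFILGJJFLJSLSMFUXMKON[RPWOQSNQRRUSRNTUQMPPSRKYLPUHOPKEGMFFGIDI?CJAA?F;:98:A;56247/*0..20+/-
@synthread04
TTTACAAAGAGGAAGTTAAGCGAGGGGGATAGCCCCTGCAAACAAGGTGGGCACCGCGGAGTAGCGCGTTGCGGTACAGCGCTAACGGGAATTTGTCGAGTTTTACGGTAGTTAAATTACCAGTTAGTAAAGTCAATTTCGGAGAACTTTAAAAAACGCTACCATGGAATTTAAGCGCTCACGCCCATCATCCCCGAGGCTACGGCAAGC
+synthread04
./.+10;8=9=<ADA=EDFIHMQPRQLQTWRPMOQSMOORRPNOSGQLVRRIVTQNNUTSROOTMOQSMQXJJPURLRROMVPTQOROLSZKNLSVXRNRPQ\UPYVQQUMROMLWNSTTOKWTUUPQTXXXKMXNNTUUQRWQNROFTRQJOUPTXQPPUSPORTTQKNLPSPKQEOUSTWQUPPMOOIJDOJ@@;8;?<45/.51,1%
@synthread05
CTAGGGACCTTACTTGCCGCTACTGCACGCTCGCGATGCCGTCAAGAATAAGGAACGCTATAGTCTTAATCCTATGCCTTCTAGTACAATCTCGCCGGAGTACACTAGGGCGCAAGTGAGACGAATTGGGTAATAGATCTGGCTTGTGGGTCAGACTGAGTTGCATGCGTAGAAGGTGAG
+synthread05
-',0,&+)-31.04,427:364434:7<66;8::76;:5965?;3/::885<61;4585<74=3?8<50=55<871:=87:4;6010>505:8:8>:64:589:49<6::5:563786218<976:4=140437;533852>6@A387>8436597<<4/:7-/1155'2-1-0.,),&&
@synthread06
TCACGGTCAGTCCGTCATAGGGCATGTCATGGATTAGCGGCCTATGAATGCTGCCACGAAAAGTGCCTAACGGCTTTGGAGGACACCTATATATCTACAGCGCATCCAACATTCTGGGCAGGTGGAATGGACCGGGTAAGGTGCGTACTGGGGTTCGACGGTACACCAGACCTACAAAGTCTTTTTACCCCTGAACGCTCCTTGACGCACAATATGTCGTTAAAACACCCAAAATTGAAT
+synthread06
&$',2443;:==:D<HHFKMMIMOSLSNRWORQLOPQSLXMDRIVRPPQPOMRPMNOXMQOMTPOKL\UUPPROQNPYTQTUXJQLSKPOTSQLMTQENSPUORROSPPOOQRRSSSPNSVRKVTOWTSMQRQONGJMONLRRTSVLOUKXRRMHSSOKPVTMWPXROUQKXT\OPUNKMVMTPQTUTSKPKUUKRLXPQRQTLVSPOIHKHWTOTRTGIQBIHC=A=:6891/26,,,*
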