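>cyclase_exemplar_synthetic role=cyclase description=lasso_cyclase_C_protein_asparagine_synthase_like_stand_in
MPHDIPSISGNFMAIPELTLQHIKVHADIGGVWFHKERYDKVVLVGQMMYPIQSAKAGNV
ELKLPQMHECSVGETEGAWPSPGGEIDKDVIIPSYLILLCEVLENDNSLAIDPLANYLPD
FTPSSDNLILTIFGVLRVTRVSAVVWTDVLWHTELGTNTLHPSPSHKNAYGSSISLNGDP
QGLGSPPTDWLLIDGNPQDYKFDSLSQTRFNGFSTSGGKGLLGEMDCLIEIAAAQTDQEF
LKVLTECRGKFPLMGVRPSDIKNPHTWSQGFTDMYLSQQNRLNLNAFGGTISETLFNWIG
VWDNCMQEGSLIPLKIKLVCPVQVRLYVLKDSPLAGEARKGFRVCAISPGWLTDGVNREQ
RGYEGNAALNSTVYEEATGQPLVFVKVTQVKEKGECAKSPCQSAFRDFDPRRPGDFNHSE
DVIEYCDVPSRVTFTPEEGGKVGQPQMQAKIFSEFQHETVYYIVSFKVFAPKVRSTVLDA
AMAANGQRLGTVWYQESGEMNNGALVVVCGRVWGLLILKNSPELLYMHGHDSCQETSSLH
AHAASMGLVGMSEGLAQSTFCAVEDFMVKSVVNPDTITRSSAMDRLTQPQ
>peptidase_exemplar_synthetic role=peptidase description=leader_peptidase_B_protein_transglutaminase_like_stand_in
MLTDQKQTVELSHKGTPPLRILCDRPFEIEPLNFAQHQAYILGKGDYELDQLKAGQLRKI
QEELLGMEIIPPNLVVRKFIFSPYVPDKEQFTPYPKFYTLYEAPLILLFTEMKASILAVA
SCFLYLASFMLKDFI
>rre_exemplar_synthetic role=RRE description=RiPP_recognition_element_E_protein_stand_in
MPRLHLGVAYFIGVGGYLWWTVNDSINLSLLADPLLNSEFWISVTVEVLRVLRTLAFERD
YTVLVGIIVCKKDENKTVPHANQLIGLLKGEN
>transporter_exemplar_synthetic role=transporter description=ABC_transporter_stand_in
MVEDLDSFADRSVAPTAHTCPSCNTDNGKFSPVAILLTWAGSASVLTRFENTPGNLTPFR
ATLDVDARFNNVNSHKELARGRGTALQTCRLYTQLTNSTEVQELNHIEHTLGQVSNVTSI
SHKYVDALDATATPEEASEQKDLNKLSAKYVWNRARKLDRIMVDIIHIEPMKISHPEVAQ
SPMCVGVVSTIILLASFLPEINLFLWRQNRTNWMDPWGRGTAVLTEVTSMSQSVLNYQLQ
SDPAIINLYVLFFSWAMRTTYLLSETLNVPKNYIMRNWLFKTGSNNGSEIGLGSIEIGVL
DVYKQPGQAL
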