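>SSRP01
QTDDKDDCYTQNAPGSLMYQIIYGHLLKFTNDKDLYCAPSQNVRVTNCKLFQCVRFDMKLHYTIYLEEWK
NPVHFIGWQSENDNNRFMRVYEKPMDHRWSVGAQMYWPITFFYKIPHQHAFMSMFNMYATFQFKWKLNFY
QEQWCLDGMAHWPSQCRYLNSAVGMRIPPANRFAAYLNGKCSTCINHGFKSG
>SSRP02
IINVQTAMEEHDMARRQKGLPQKMWQYIRPRIKHQEDKEDARWWNWEVHKYCIRQIIGSKLYKEKHAHSM
RVGLLFPNLDNMRQSPMLFVQWRNFTNGEYWCTFMKPIYKVRPQPPNVNRKQMHVCYMAPWFNVAFNVAV
TLRNFNHNTPIRLKWYVGINSPSAY
>SSRP03
ASANTHDAMNNMRAYCMLIDWHTTFPWTPHGKNWWEGQGGYCMQWQHDAQWLRAWAVEESKRHEDRMRCG
SNSHPTDEPMKPEEKTEYLTVGKLCQCCHIQKADHGMTCNQKPLEQVEVGFFLTMCWRVWGGQVMKPGHN
PMN
>SSRP04
NLNRNFKIHHWIAADWEYIPQNDFDTYFTWHNKQTIGIIWQSRSDISPCPHKHMHTMCATMRKSSCSMKF
RYLFASCRNHWGNAWYQWEDIICQIYAEQRIVWSYMALQRDHCRKRLSAKSFCCWAPGMVDMFTVYFTSY
MGKVSEQPQDRVPQFTNKGRNPTCFMRRFNFGRYRAEGTHPHNRSHRKYNMRKGYNRTVHDYGNGCNGLK
MSWRNIHHGFSRYSQSNIVC
>SSRP05
CWDSYMWGLKEKTQVCFNSKSIQFPEQDHCPMCIVAHCQMKWLLERFSVNLYKSMRGRCQNLKANSAVVY
SEDTISFRKRHRFLDYEGYEIPANFHPEFCYAVYGNRERVIVNDWVFIRKYLYWN
>SSRP06
QPSSNSYMYLMGYMAWLPMSQLAFTRLPHCAYYMACKGAQRLWYCLTFIWRKFVRTWKKMRWATNGCTQH
LVTLAQEFVNPTVVRTGAKMKIECHDISDIHNLELLRMVVMQMSVWTYFCDILNCDQHWDKFWLDFPFYE
QHRNYCQMFWTISQMCNKCQREHYRLYQRCKCDQYEYQWHDNWDLESH
>SSRP07
LCYHGEEPPIMHHEAQVWPFALIQNRDHCMQVKEFRWCYIYWGFLIQKKQPHTNHSIPIQPMCYTGEWDA
VKETHRMQRAVEAIRRYEPDHIMKICQKNPVAKWETRAHTPCHYFYMEKLVTHQQQKWGAALCTHNAMHH
HIYSWVFANVNPSKAINSMERDSEKLILRPDFGRCTCILQFMR
>SSRP08
DHVNKVQQATYGTPQCQAVVIVQPLQFRDTSKRHWDDALVHPKVDYMPVCWRRKHLNSWGCIVGKIYFDM
YVMETHGHAMGCDCFVIGIQIIHEKINTAPCMIEQITQRAAWKFELDCIYNALVPPPGNKYYYAYCTPIN
VAGPQGAQRAEIQYAGHYQFEHIGQRIACTGTCHVEFMLESYERRATWDVA
>SSRP09
LYSMTMWVVDSKCCSPYCNITICMRNRRGCTVQHPSQDQLKIYKLASARDSPWLLDKLCEQHPNPNCWKM
QQMEYVVCISIVCFSYPAPEFSRKAYNYDRTLWLVDCMPMMCAKMWNKPPEAQYAVPPAWAQDWCMSHVV
PLVKNLIEGSLCIEWWDQLFYSMQHHETIYIQWVYAWHENEPQRNKELDSRVDDKWDMHAMYQCKKKEWH
AARDAWLRINTQEIVAFSYPICDGHTMIEMAIE
>SSRP10
YKDMQVCDVLSECMIPFIETELNNCEDDVQDISFQCQSNNPQTSPESEYIEVTHWQCDEEPDNMELHNSF
CCYQNTFNMFMFSKEATACYYCPYCSNPDKKRVKHGQTTPKAPYYFYPTWRPFKRAYFRIGMFWQEDWCT
RTLWNKIPHKESFAQRWF
>SSRP11
CPGAQRGCETTQFQLFDRTRWPGQLNSQSAMYDLHQLSNIFEWDHFETNETNVFCFDPNRCNSVLISPQY
TEPILFCWCRTQYPARCGIQPILPKWLIFPAEKEWTDEKWFPNSFLAPFPMHYVKTPHAFIRERYMRKMP
KPKIDTVNHGNRHCWHFLFCAVKSQHDKYNTMNLATVRVIARRKVLYPSISEMQSTVWM
>SSRP12
HGIKYVQARMIQIHMAHADWWEYKGLVRAIMYLWHKYRLTRAPNFRNANIFSCHIQEHYFFRLVPCDEII
KFDKNACNCCWTEQESYWQQHNVPEMRSKGRPTYQFMPGIARGPLPRRPLYPQWWSYHTVRSVAAINRGL
QGPDSCKNTDAFWYNNWHCDCKIDQCTCYNDGYQQWWWSQWAKLWDQPKKCRPRWDDILAFEI
>SSRP13
APTEVVHGIMSLQHQADDLTVFNLTDWVWHSGDTEVHIPIPFPRKAYVRTCKCGCRTSCPYQYDAYQIRH
VTPALKFWPRMGHKFMCTIKDCRLWQCNACVSAMWRCHSNHNGDRVGFDWCPWPHNCCDMIWMFMKHGQD
RMLGWPSYAIEAYCGYSRVAKYNQGQYYCHVPVPWRAFCFWSLFDSFYWMTSYEMALLWWEFCGFFKVIN
CRTLDPKIQGQYMWCWYNKEWGLDMIEELNEQ
>SSRP14
YILAIMWQINTSYRGKNAIYHVTNVWANWFHFVNAYNGEFRDMVMAMHNPYKNKSRHGSCDRKFMMESQM
DLHSKADSWKRWRIYVWKCHQDSQFYLIHYQTEYFYQSVSRKHASSCKDQYAFSRKKVFHLCEYINNRCW
ILFHPVKESAPIRYMVRI
>SSRP15
TSPKFTTHHSKEGADVFKGEHRPNDKWHNQQYKRIGLWYNVDGELQYVLKLRQGMWHDVQQCFDHHEHEF
RCNHIQQQHNSWFASKHDYNFSVIIYSMELCCPPPQFRDQIDCHSARCWDKMWQTIGWGPLYMGFDYKEN
AIQEKQEWQYLRDPCLGSYMQVEQFDYRKQYVHNYTLKTCQWMWDTCCWDYNWREYHPEEQTASLENMCL
REFQGKV
>SSRP16
QFATNDKQNTVHLVCKGSQHAWYGWGVKCFDPEERKPCPSVFLHFVHCSQRYRPYQQHTKWKRCSYLPYW
EQANAYHHLDSGLNTTQFLLHDKHNYDIKMTCPFKEVHAKRHETHKKNIPFTTWWADHMKLIQHDNMNVA
YHNLHNIEMGRQPVVQCMPTSYQVYQLL
>SSRP17
FLCPNESKEDGANQGQPGRRTIQLRQCLTYRIYMNHGKQMCCVLIGDVFKKANCTWQTQWTAIALSQDEI
DHKLGHIPHYKFKTDMPNCKTTWAQTPRGLAYLLWSPYGVVLYIDNLWDAQE
>SSRP18
NGEQTWINCHISVFILMAGPAIYRRMGYPIHICQTNHPCLLGECCTRRMCDVMNRNNHARRKNCQFWNYD
FHLLMWSKTQSHFPYNFPMFELTCLLAKSLMIYGALFIGVTPRIGDTTVTVRPKRAGKRYDIPVNACMAG
CPDI
>SSRP19
GWMGDGSAGARNIGRDCHLKFFPQSIFNHINTSWCLVNCWVGCEFFIQTDFKFTRWKIFVADAWNGPDWP
QKDLWQQDSMHRYKKCYSCDPNCCGTCTHWGGREPKLIVLLWWCHTDNMKCLLGVVMQCPFDCIRLQPCR
STQIASTVCKWIRTLTAQLDLDYLIVFPGKRGKSMQFTWKQGYTHKTNEYKSQSNYERF
>SSRP20
AIMDDPRIDQQYDQPSESMRTQTQDHLDIECETHAPTCDISSWNSLWSGFDGLAIVHMIVMRPLKKPCQM
MCCPRVWANPIMTPEADPNSPERDSARVWEMLRAHQQEQTCKRLHIIWLIMKTEMENFHRDHHEPEGVWE
HSMNSHGHKQADMRNAMRMKRSMNENDWNMTY
>SSRP21
SIVTHTLSVDPTGPPFIEFKLADANRPLSRKNYALQNILVCQRVMVHNCFVIWPQNMSEIRDEECLANFK
QFAHSGAQARMIITMPGKMGWPEYFQDIQSLPVPPNGDDLNFWHNGYWRPLWELQICRKRHTYITGDETH
IAPRPQSETRVRDMTNDNNFWVLTFKFRPQQYNSSMKYAFFIHVYAPRSKYATKDEQAGNMWFHNFCLWE
TADQHANWLRH
>SSRP22
VDNVVSKFFHRVHKEFFLPHWHHHNIDTNFVKDIAFCPAWIDHSWQMSKIAGERNFGDELRMRHIFHWGI
PIVNKIPLPSWHCCDAMSAAHIYSTQSRFFIYECWERSWKPACDIGCGPHQHFRELKITAWKEVQIRCWL
FTCDNTNCFQRNAKGEAKAQFRWRKVFGWTCAPQLHVELQKCFY
>SSRP23
RRFRHLKQPNRFNCNCMPFAFANECVHLVLWKQVMAPWFWEVWLPNFSAKCWQQAGNLGSSKYNCEEMNT
GPTMPERLKPKKVYNVWSFQHSAGATMPECTYCSRWDPSRERKSDVFPTLCKYNRSPASSQQLQTMAPAK
SEGHFCGKHGVAGPTFW
>SSRP24
PNGMWVDMMSWLSAWSWNCPFQGLTMMKSIWGAPSLKYHTLTRAWHQKMRHANRQPHKEPGTMSNFFCAA
DIKLSNMSCSRMITNEMDWPRYDRKCQVLPSLRECPYLAWRAANRQSGHMEFKNTQEEIIWVGWSHLFYG
PDKWDDCKVCLMGTPDINEERIEINEFIMRYDEHNNCKAHCPQFTRHIDMYIVHKDM
>SSRP25
RVAWVFNGMIARPYHDYCGYIHVPMCSENEADGRSHKVYKDPLRILSAQFEEAPNYGGKRTFWPQECPTG
DMLAQNGIPIGENRNFDCVLGAGFKRLEGRQHRRSMYKCPPQQVFNPELAFKDWPFPYHKTPQGRNGQMA
KSTDKHYPLWHTKNCEKLGNGCLHHIIEDMHWTPKVTWIGIEEMVITSSYEQIQGLLDWKHYVAWADPYW
SVSTTFRGHIMQICAELGMHQNRHCQHEEWKKLPDAIAE
>SSRP26
MICPPRQSNHYNHQFEYHKSKQCNYAHKDGHALIKWIENCHWYWPKHHIPCTKKPLGNLCHETMGTMQME
FCWHWIDLLMLCCFCVHRDWMDECYCSREYSHLFEAAWDCAQCMKKKPYVFDHQYLDPEHFIHDMFETMM
KQMPDDEDWHCMQTALKQPVTKESNLIPSSSDPPRGANFDLGLHLRPWPGCVNQAVWMTADWSAARFQRM
VHAGYWYENCIHFAYSRRP
>SSRP27
WYLHLTKRIVPTWCKHYEFAGLNHRPGVGYNLPRRCCLFRSHGIQEVHHIHPFQDQNCNMCWMPRCGLAK
DFSLNQQDNEEYSKQVCQIKTEGRIMMFIWWKENQAHVAECPKIRMEYLITMHIGSSQDSRVWKKWRPSD
RVDYRK
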