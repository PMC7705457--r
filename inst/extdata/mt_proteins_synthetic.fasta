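>MT-ATP6 synthetic stand-in sequence
QPMTWFLLALFPTLSSVFTVFAHNGPTAILITFPAPTPAMAALFEQYSNFATIMWRTFFMLVNEDIAFIT
MAIHNMEFPAYWATSECVGLMIILCHMGALNYFQYMYGDGSRWWCAHLTMFNTSKTDSNWGYILIRSVGI
GHSWDFSTADPYVAFAGWIFMCVENVLNWWLLTAFMFRFIIVDFWGHTVWVILDLHSMDWLIKKIATINI
AMHTSESISCPYIRAW
>MT-ATP8 synthetic stand-in sequence
TVILLYSANHWMATPYVTLAQLLLAPIPTINYGWYSDIEIQVLTIINLLWWEAGPVMELSYPSLLYGM
>MT-CO1 synthetic stand-in sequence
QPFQGVLDYVCPIEAILLWKSVALILFLILAPIPNNYMLAYALSSWSFELGGFARMENRDAALTIPTLEG
NPQKDGGWIHMVLLPSMNIGFKTYPLAAFTIFATLFTFLFLRFLCEHEAIKVLINKRKACSVYTALVLPM
VVDMPAGHIAISNFITIMAPTGDFLNVLTASQGTFLAAYWLLGLTMPTIPTFSPLVVTFILSPSVSSMSP
WNFFWGIYGAMLGDIHNSHITFWNNLLYLPWITFIFTAILFMTYAAKILSFATWSRLLLYVMILNFFEHE
ISTMLNPLVWLYIITTYPPLRFCLAWALDINLTTDTNLQQIIVVILLIIIILSIVLMVSHNAEAILISAM
VHANIAAAVFMKMVFAAYNIICGPLMTVNSLPAMPVELRITLDLTILYLWTWFAIQELLAESWAGFLISV
LISNNMLFMPTIKDLNNGPVSLTITINTTKGFLGWKPAYPKSTLITYHGYSRSLALINDKEDACDISVCG
KLRALVLARFIWRIYTPNTSSGA
>MT-CO2 synthetic stand-in sequence
DYLTSVLDPATIMRLASCVLEIILPTFVYLTIIMNFHPSEASIRLLGYETLMFFFCEINSQMKMSTFNVA
YTGCILIWLRYFFYTYDSWIACFEAVHGNVAYNPFEWGLAIVEWMLWRLWPLLRTRHIRRLYVTNSRARL
GWPILMYALGELWDTINVACSLLVLGWCLTYELTIHMRFVLLILVTLFAAHLAKIPLLSNVVTVAVLRLG
SHMQAFCIMFEWLPSTL
>MT-CO3 synthetic stand-in sequence
CLMSKAENAHTFLRNLLSLYITFIGVYGLLPIAAKYVDSPAAMHLEMVYLTRMLGRVTLPLLGVGYVLSE
TISAIMMTDIALLATLGHFLSLPWYYIRAVYFAFEFMLCGTLYGNFAFLALFPCLKGILFWLLLTNALCV
LLQRVINLMSHMISSMRNSFGQILLCFFTQRENIQHTVLWIHALNMRTSSHFALTYYPGIWWSTHMLAAM
LVPFLMNWLWVFFVFNEIYRLLSGSAIDMKKRAMSLLRFSWGFVVMKTLFS
>MT-CYB synthetic stand-in sequence
VIFDFIHFTLPPCMIVQAGHLYGWRIMEWLPMWTTKFAFNSVITLYLLVPMAPSLFMNMMKRCHYRKQHA
YLRSAYSTTTGILTTLKNITGITNKMREVSEPQIIEACFGMYIKLMFLLVGGTPDDFWMRLTLIKWIQLQ
FASGNDTWGPYNFVNSNLILWPLAKGHSTIWYTNTESFYPWMIAILGIGVLNCTSIGWNTWLDLPHAMLL
PLTALIREPIIITLLYTILNFELLSNSLMSIPFNLHNCILYAEVAIARADILLSRNPNNFLLVMCRIRSV
NWSLHAADIVYHLLAIYTGTLHPTLYSLYLCWENFIFFSTALPKMFITLITATFNFDAVDSMLPNFYRSI
VLSPSQMRYPIFGHAPLLLHPILVSAICLL
>MT-ND1 synthetic stand-in sequence
TITTMVPALNYILLMPIVKFLQGAPHELLWNLFSVTTFFALLQPKKLKQIPMSMFTVLMILRILLLDGAE
ETMPTSMYARSLVLLLVVAQANNTAFATMAFILKIFILQTGENHAIGTFAINNLTIYQQLEDHMIFYRDL
ETAWATAKQIAIMVSIPAIYMTLMNPCICAPLMIDAYSISLKAITSFHKVLKDDSIFSLIGPIFDGTSNN
SVFYVMVVTHECLEFLFAICTGDTADAEDIIDIEMLSSGLVVLFVIKALMPIRFVIRAYFFALENIILQV
SHISTILLQIELMWATVALILPPGIVILISMSLNYTLF
>MT-ND2 synthetic stand-in sequence
LKQAIWTVFVLNSASMYIHLEDISTPTFDALLATYLSFNVCHYENQPILLLFALYVITPGLDYYRALILL
NYMNYYPLIFMLTKMWTWQMEVEIPALNMTIFVNSFDMLMRMMYMNHNLFNYKLNGWIDTAMMSFDTTLL
WALIEFAAISLKWAYANHPTSIKESCFYVVLDFDYSGGNAQSWLIGLCQATQKFQPHLLLVPSQSHKIQG
DTSSRHACLVMYLFYGSIAVAILPIEFSLMTVLMWTFIGCSEEESSLIIFITLWCIALTIPHSTLIWAAL
VLEETILPTFLFVWIVGHPLHVPSSNSNLGLVWVYTLSYTFQELIPTRAYPCIEVIYTFWTAGSTIT
>MT-ND3 synthetic stand-in sequence
QLFDYCYSLADNRWTTSIPPWETFNGNQALELPIGQLAYHNQLPLHGATLIMSNITTNITLALKIGSNYD
NITLQSRASCSWTKPTLCCCMIAGDLRLLLTGLIFIWLAESHALN
>MT-ND4 synthetic stand-in sequence
FNLCISRTFEHVHATYYTQLMWGFTTYNFTPFSNFIMWPTLMVTNFTYCIGILTDSGWAGLFLRSVLYEN
LQLFTFTLLPGEYEKSISCFSITTNNNLYSLAELSPVEAFTSMGFANTFLHCWTDELPSFLVYVYNLLLH
ELDFAVTSRFSPSKLVITSSSIGLGSVLIIFHQTNGYYDYEIMIKVHYVECGLYIAPLQPNAIQTSMTGG
LDLDKELWKTTQTFILYFRLTAYRLLLVTLIELYFSWCWRLITTWVLFGLRANSTLQQLVMYITSEKLPA
MLPAIKFIEGWMFTFSGSIMLIILEVMRTYLNLEHAQSPLVTMIATLELVISLVFVVAWEHALEMGFDLV
CLMLKIGYPCWLFSVSMSIITLHPNLQWGTLPSYYTIVAKYMIALLVCAATILIANTTRRAVTYRANLVL
VGEVAYFWFWTVVFISIPKMAPNQENSGLTILKFSPINL
>MT-ND4L synthetic stand-in sequence
SPVFVLIPMIQLSWIHIYIKESWHAFITTYLVVFWMTRATSITAVLMNSETAMNSLISLRVPSESLYMRV
IQEPLGLTKMIIRLCSKVLILDLHGKSE
>MT-ND5 synthetic stand-in sequence
LSGRLIPNFQTINVFLNLQTNYFLFAYVATRAADKITYLELSTAFLLWFANVIRLIWNLLYNREFFMAIA
TLWAMEIILTQTYTNMNVLYLGLLGIPMKLLHLTQNLNLNALMISSTFSLALSHWAVLLISSLSWLGNLL
LVGLMYYAFMPAIREGLRKYQGILVGNQWAALGPVWSNLSTIEPQTTTSALCEFAVLIHSDSHLLNLKFE
PREFVVILRVLTVLHCWDIMQMCLLFAGLLKVKRALEVIYTGVYYQIILLITYYCELLNPLFAQWIDAAP
NQCSTNRLVHWLKTLAEFHITNTLLIIPILMFQDGPICISKLTAVCWILWQWIHKGELILVTLSLCFIYT
IAAYAQLMIMNMESLHNTNHLIWQGAPLQDQQSSSVLYLWSTLTLVSLLPPWPSNWLLPDSVVLTTRTSW
LITTYTIGAYATTASWYLPLAVQIQLFLARFRSPVNQKKVAISFTHDLIAMATFGISLLGNIELDWLRYL
LIVNDELVKQLGATLFIMPNNGSGSILKLWMLHEMANSTLPEPAIEAMDNINGPLYSNHHAIEFLLALGV
AAKEAHFVILLLGMHAWVLNPSGGLFLMVVSMVWMVHVKIPRD
>MT-ND6 synthetic stand-in sequence
NNCGIWSPSTLAIQICQNATGTGPFLLRLPYYTIRKAHENSNFGTLAFLLNHRTDLCMVSLAWTELSPLS
SIGTIYLPPPNSTNLTIQPSALVKYNLSKQPILLVIAQPHLEWHMNGAYSSPIELMSLSPLLAQIIMNCY
RFWFQLNPLPHAQILVLVSTGLALSFVIMLIIID
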