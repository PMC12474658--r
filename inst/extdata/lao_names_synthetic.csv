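"lao","latin"
"ຈັນຄຳ","Chankham"
"ໄຊມະນີ","Xaymani"
"ດາວສຸກ","Daosouk"
"ຄຳສຸກ","Khamsouk"
"ທອງລັດ","Thonglat"
"ວັນສັນ","Vansan"
"ແກ້ວວົງ","Keovong"
"ເພັດທອງ","Phetthong"
"ມະນີສົມ","Manisom"
"ນ້ອຍສັນ","Noysan"
"ພອນນ້ອຍ","Phonenoy"
"ດາວວົງ","Daovong"
"ນ້ອຍໄຊ","Noyxay"
"ບຸນຈັນ","Bounchan"
"ເພັດດວງ","Phetdouang"
"ສຸກສີ","Souksi"
"ບຸນສີ","Bounsi"
"ຄຳທອງ","Khamthong"
"ແກ້ວດາວ","Keodao"
"ແກ້ວສີ","Keosi"
"ດາວນ້ອຍ","Daonoy"
"ຄຳໄຊ","Khamxay"
"ລັດດາວ","Latdao"
"ບຸນແກ້ວ","Bounkeo"
"ຄຳສີ","Khamsi"
"ວັນດວງ","Vandouang"
"ພອນລັດ","Phonelat"
"ເພັດສຸກ","Phetsouk"
"ນ້ອຍຈັນ","Noychan"
"ນ້ອຍພອນ","Noyphone"
"ຄຳພອນ","Khamphone"
"ວົງແກ້ວ","Vongkeo"
"ພອນວົງ","Phonevong"
"ຄຳໃຈ","Khamchai"
"ຈັນບຸນ","Chanboun"
"ມະນີແກ້ວ","Manikeo"
"ມະນີສຸກ","Manisouk"
"ມະນີພອນ","Maniphone"
"ວົງສຸກ","Vongsouk"
"ລັດທອງ","Latthong"
"ພອນຈັນ","Phonechan"
"ດວງນ້ອຍ","Douangnoy"
"ຈັນສົມ","Chansom"
"ມະນີລັດ","Manilat"
"ສີແກ້ວ","Sikeo"
"ໃຈສັນ","Chaisan"
"ລັດສຸກ","Latsouk"
"ວັນບຸນ","Vanboun"
"ລັດໃຈ","Latchai"
"ສຸກໃຈ","Soukchai"
"ສຸກລັດ","Souklat"
"ສັນແກ້ວ","Sankeo"
"ນ້ອຍເພັດ","Noyphet"
"ທອງສີ","Thongsi"
"ສັນດວງ","Sandouang"
"ລັດມະນີ","Latmani"
"ໃຈບຸນ","Chaiboun"
"ສີນ້ອຍ","Sinoy"
"ວັນລັດ","Vanlat"
"ດວງສັນ","Douangsan"
"ໃຈສີ","Chaisi"
"ສີລັດ","Silat"
"ຈັນດາວ","Chandao"
"ສັນສົມ","Sansom"
"ໄຊເພັດ","Xayphet"
"ວັນທອງ","Vanthong"
"ລັດໄຊ","Latxay"
"ສົມທອງ","Somthong"
"ດວງເພັດ","Douangphet"
"ດວງທອງ","Douangthong"
"ທອງສຸກ","Thongsouk"
"ສີວັນ","Sivan"
"ດວງສຸກ","Douangsouk"
"ດາວສົມ","Daosom"
"ນ້ອຍສີ","Noysi"
"ສົມພອນ","Somphone"
"ລັດບຸນ","Latboun"
"ບຸນວົງ","Bounvong"
"ສຸກຄຳ","Soukkham"
"ຄຳເພັດ","Khamphet"
"ວົງໄຊ","Vongxay"
"ວັນສີ","Vansi"
"ທອງສົມ","Thongsom"
"ສີສົມ","Sisom"
"ບຸນນ້ອຍ","Bounnoy"
"ດວງຈັນ","Douangchan"
"ສີເພັດ","Siphet"
"ແກ້ວພອນ","Keophone"
"ນ້ອຍສຸກ","Noysouk"
"ສົມດວງ","Somdouang"
"ສັນເພັດ","Sanphet"
"ວັນເພັດ","Vanphet"
"ດວງດາວ","Douangdao"
"ວົງວັນ","Vongvan"
"ຈັນສັນ","Chansan"
"ແກ້ວມະນີ","Keomani"
"ໄຊຈັນ","Xaychan"
"ບຸນລັດ","Bounlat"
"ໃຈສົມ","Chaisom"
"ໃຈດວງ","Chaidouang"
"ໄຊວົງ","Xayvong"
"ວົງມະນີ","Vongmani"
"ເພັດໃຈ","Phetchai"
"ລັດເພັດ","Latphet"
"ສຸກແກ້ວ","Soukkeo"
"ລັດນ້ອຍ","Latnoy"
"ສຸກໄຊ","Soukxay"
"ທອງພອນ","Thongphone"
"ບຸນສຸກ","Bounsouk"
"ສົມຈັນ","Somchan"
"ວົງນ້ອຍ","Vongnoy"
"ເພັດນ້ອຍ","Phetnoy"
"ສຸກບຸນ","Soukboun"
"ພອນສັນ","Phonesan"
"ວັນດາວ","Vandao"
"ບຸນໃຈ","Bounchai"
"ມະນີດາວ","Manidao"
"ນ້ອຍໃຈ","Noychai"
"ເພັດສັນ","Phetsan"
"ຄຳມະນີ","Khammani"
"ໃຈສຸກ","Chaisouk"
"ເພັດຄຳ","Phetkham"
"ນ້ອຍລັດ","Noylat"
"ເພັດບຸນ","Phetboun"
"ສົມວົງ","Somvong"
"ຈັນເພັດ","Chanphet"
"ໄຊນ້ອຍ","Xaynoy"
"ໃຈມະນີ","Chaimani"
"ວົງລັດ","Vonglat"
"ສັນຄຳ","Sankham"
"ສົມຄຳ","Somkham"
"ນ້ອຍດາວ","Noydao"
"ສີສັນ","Sisan"
"ດາວສີ","Daosi"
"ດວງວັນ","Douangvan"
"ດາວບຸນ","Daoboun"
"ດາວຄຳ","Daokham"
"ດວງລັດ","Douanglat"
"ສີໃຈ","Sichai"
"ໃຈລັດ","Chailat"
"ສຸກມະນີ","Soukmani"
"ເພັດວົງ","Phetvong"
"ນ້ອຍມະນີ","Noymani"
"ວົງຄຳ","Vongkham"
"ຈັນວົງ","Chanvong"
"ໃຈນ້ອຍ","Chainoy"
"ມະນີດວງ","Manidouang"
"ເພັດລັດ","Phetlat"
"ທອງດາວ","Thongdao"
"ເພັດດາວ","Phetdao"
"ນ້ອຍແກ້ວ","Noykeo"
"ລັດພອນ","Latphone"
"ວົງຈັນ","Vongchan"
"ຄຳສົມ","Khamsom"
"ວົງໃຈ","Vongchai"
"ທອງດວງ","Thongdouang"
"ດາວໄຊ","Daoxay"
"ສຸກດວງ","Soukdouang"
"ສຸກຈັນ","Soukchan"
"ພອນໄຊ","Phonexay"
"ຈັນພອນ","Chanphone"
"ມະນີນ້ອຍ","Maninoy"
"ວັນມະນີ","Vanmani"
"ໄຊສັນ","Xaysan"
"ສັນທອງ","Santhong"
"ວົງທອງ","Vongthong"
"ບຸນເພັດ","Bounphet"
"ສີມະນີ","Simani"
"ສີໄຊ","Sixay"
"ສີດາວ","Sidao"
"ພອນບຸນ","Phoneboun"
"ວົງພອນ","Vongphone"
"ວັນຄຳ","Vankham"
"ໄຊສົມ","Xaysom"
"ດາວທອງ","Daothong"
"ມະນີເພັດ","Maniphet"
"ແກ້ວດວງ","Keodouang"
"ລັດສັນ","Latsan"
"ບຸນທອງ","Bounthong"
"ບຸນພອນ","Bounphone"
"ຄຳວັນ","Khamvan"
"ຈັນດວງ","Chandouang"
"ສົມສັນ","Somsan"
"ມະນີສັນ","Manisan"
"ຈັນນ້ອຍ","Channoy"
"ສີພອນ","Siphone"
"ທອງໄຊ","Thongxay"
"ດາວພອນ","Daophone"
"ສົມສີ","Somsi"
"ເພັດມະນີ","Phetmani"
"ບຸນສັນ","Bounsan"
"ທອງບຸນ","Thongboun"
"ສຸກວັນ","Soukvan"
"ພອນຄຳ","Phonekham"
"ໃຈເພັດ","Chaiphet"
"ສຸກດາວ","Soukdao"
"ພອນມະນີ","Phonemani"
"ວັນຈັນ","Vanchan"
"ໃຈຈັນ","Chaichan"
"ສົມໃຈ","Somchai"
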